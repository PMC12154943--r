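#' Read and write scheme configuration files
#'
#' Schemes are stored as JSON with top-level keys `units` (fixed:
#' concentrations in `"uM"`, time in `"s"`), `species` (list of
#' `{name, initial, roles}`) and `transitions` (list of
#' `{name, sources, targets, k}` where sources/targets are
#' `[species, coefficient]` pairs). The writer emits keys in this order with
#' deterministic formatting, so files diff cleanly; `read_scheme()` followed by
#' `write_scheme()` is the identity on the data model.
#'
#' @param path File path.
#' @param scheme A [kin_scheme()].
#' @return `read_scheme()` returns a [kin_scheme()]; `write_scheme()` returns
#'   `path` invisibly.
#' @examples
#' sch <- build_scheme("scheme5", E0 = 1e-3, kon_I0 = 1e-2, koffapp = 5e-3,
#'                     kinactapp = 5e-5)
#' f <- tempfile(fileext = ".json")
#' write_scheme(sch, f)
#' identical(stoichiometry(read_scheme(f)), stoichiometry(sch))
#' @name scheme_io
NULL

#' @rdname scheme_io
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "kin_scheme"))
  pairs <- function(v) lapply(names(v), function(s) list(s, unname(v[[s]])))
  obj <- list(
    units = list(concentration = "uM", time = "s"),
    species = lapply(seq_len(nrow(scheme$species)), function(i) list(
      name = scheme$species$name[i],
      initial = scheme$species$initial[i],
      roles = as.list(scheme$species$roles[[i]]))),
    transitions = lapply(seq_len(nrow(scheme$transitions)), function(i) list(
      name = scheme$transitions$name[i],
      sources = pairs(scheme$transitions$from[[i]]),
      targets = pairs(scheme$transitions$to[[i]]),
      k = scheme$transitions$k[i])))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = 2)
  writeLines(json, path)
  invisible(path)
}

#' @rdname scheme_io
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) stop("scheme file not found: ", path, call. = FALSE)
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("cannot parse scheme file '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  for (key in c("units", "species", "transitions"))
    if (is.null(obj[[key]]))
      stop("scheme config: missing required key '", key, "'", call. = FALSE)
  get_field <- function(rec, field, where) {
    if (is.null(rec[[field]]))
      stop("scheme config: missing field '", where, ".", field, "'",
           call. = FALSE)
    rec[[field]]
  }
  species <- tibble::tibble(
    name = vapply(obj$species, get_field, "", "name", "species"),
    initial = vapply(obj$species, function(s)
      as.numeric(get_field(s, "initial", "species")), 0),
    roles = lapply(obj$species, function(s)
      as.character(unlist(s$roles %||% character()))))
  if (any(species$initial < 0))
    stop("scheme config: negative initial concentration for species '",
         species$name[which(species$initial < 0)[1]], "'", call. = FALSE)
  side <- function(lst, field, name) {
    raw <- get_field(lst, field, paste0("transitions[", name, "]"))
    v <- vapply(raw, function(p) as.numeric(p[[2]]), 0)
    names(v) <- vapply(raw, function(p) as.character(p[[1]]), "")
    v
  }
  transitions <- lapply(obj$transitions, function(t) {
    nm <- get_field(t, "name", "transitions")
    k <- as.numeric(get_field(t, "k", paste0("transitions[", nm, "]")))
    if (!is.finite(k) || k <= 0)
      stop("scheme config: transition '", nm,
           "' has non-positive rate constant", call. = FALSE)
    kin_transition(nm, side(t, "sources", nm), side(t, "targets", nm), k)
  })
  kin_scheme(species, transitions)
}
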