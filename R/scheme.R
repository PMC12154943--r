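#' Species role tags recognised by occupancy metrics
#'
#' Role tags attached to species so that occupancy observables can be computed
#' without guessing from species names: `"free_enzyme"`, `"free_inhibitor"`,
#' `"noncovalent_complex"`, `"covalent_complex"`.
#'
#' @format A character vector of the four recognised tags.
#' @export
kin_roles <- c("free_enzyme", "free_inhibitor",
               "noncovalent_complex", "covalent_complex")

#' Define a mass-action transition
#'
#' A transition converts its source species into its target species at a rate
#' equal to `k` times the product of the source concentrations raised to their
#' stoichiometric coefficients. Units of `k` are s^-1 * uM^(1 - sum of source
#' coefficients): s^-1 for a unimolecular step, uM^-1 s^-1 for a bimolecular
#' one.
#'
#' @param name Identifier, unique within a scheme.
#' @param from Named numeric vector of source species and positive integer
#'   stoichiometric coefficients, e.g. `c(E = 1, I = 1)`.
#' @param to Named numeric vector of target species and coefficients.
#' @param k Positive rate constant.
#' @return An object of class `kin_transition`.
#' @examples
#' kin_transition("assoc", c(E = 1, I = 1), c(EI = 1), k = 1e-2)
#' @export
kin_transition <- function(name, from, to, k) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  check_side <- function(x, side) {
    if (length(x) == 0L || is.null(names(x)) || any(!nzchar(names(x))))
      stop("transition '", name, "': ", side, " must be a named vector", call. = FALSE)
    if (any(x <= 0) || any(x != round(x)))
      stop("transition '", name, "': ", side,
           " coefficients must be positive integers", call. = FALSE)
    stats::setNames(as.integer(x), names(x))
  }
  from <- check_side(from, "sources")
  to <- check_side(to, "targets")
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
    stop("transition '", name, "': rate constant must be a positive number",
         call. = FALSE)
  structure(list(name = name, from = from, to = to, k = as.numeric(k)),
            class = "kin_transition")
}

#' Assemble a kinetic scheme and its stoichiometry matrices
#'
#' Builds the source (`N_src`), target (`N_tgt`) and complete (`N = N_tgt -
#' N_src`) stoichiometry matrices for a Markovian mass-action scheme. Matrices
#' have one row per transition and one column per species; column order follows
#' the species table, row order the transition list.
#'
#' @param species Data frame with columns `name` (unique identifiers),
#'   `initial` (non-negative initial concentrations, uM) and optionally
#'   `roles` (list-column of character vectors, or a character column of
#'   comma-separated tags from [kin_roles]).
#' @param transitions List of [kin_transition()] objects.
#' @return An object of class `kin_scheme`: a list with elements `species`
#'   (tibble), `transitions` (tibble with list-columns `from`/`to`), `N_src`,
#'   `N_tgt`, `N` (integer matrices) and `k` (named rate-constant vector).
#' @examples
#' sp <- tibble::tibble(name = c("A", "B"), initial = c(1, 0))
#' kin_scheme(sp, list(kin_transition("decay", c(A = 1), c(B = 1), k = 0.01)))
#' @export
kin_scheme <- function(species, transitions) {
  species <- tibble::as_tibble(species)
  if (!all(c("name", "initial") %in% names(species)))
    stop("species table needs 'name' and 'initial' columns", call. = FALSE)
  if (anyDuplicated(species$name))
    stop("duplicate species names: ",
         paste(unique(species$name[duplicated(species$name)]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(species$initial)) || any(species$initial < 0))
    stop("initial concentrations must be finite and >= 0", call. = FALSE)
  species$roles <- normalize_roles(
    if ("roles" %in% names(species)) species$roles
    else rep(list(character()), nrow(species)))
  if (inherits(transitions, "kin_transition")) transitions <- list(transitions)
  if (!length(transitions) || !all(vapply(transitions, inherits, TRUE,
                                          "kin_transition")))
    stop("'transitions' must be a non-empty list of kin_transition objects",
         call. = FALSE)
  tnames <- vapply(transitions, `[[`, "", "name")
  if (anyDuplicated(tnames))
    stop("duplicate transition names: ",
         paste(unique(tnames[duplicated(tnames)]), collapse = ", "),
         call. = FALSE)

  n <- nrow(species)
  m <- length(transitions)
  N_src <- N_tgt <- matrix(0L, m, n, dimnames = list(tnames, species$name))
  for (i in seq_len(m)) {
    tr <- transitions[[i]]
    for (side in c("from", "to")) {
      coef <- tr[[side]]
      unknown <- setdiff(names(coef), species$name)
      if (length(unknown))
        stop("transition '", tr$name, "' references unknown species: ",
             paste(unknown, collapse = ", "), call. = FALSE)
      mat <- if (side == "from") "N_src" else "N_tgt"
      for (s in names(coef))
        if (mat == "N_src") N_src[i, s] <- N_src[i, s] + coef[[s]]
        else N_tgt[i, s] <- N_tgt[i, s] + coef[[s]]
    }
  }
  structure(list(
    species = species,
    transitions = tibble::tibble(
      name = tnames,
      from = lapply(transitions, `[[`, "from"),
      to = lapply(transitions, `[[`, "to"),
      k = vapply(transitions, `[[`, 0, "k")),
    N_src = N_src, N_tgt = N_tgt, N = N_tgt - N_src,
    k = stats::setNames(vapply(transitions, `[[`, 0, "k"), tnames)),
    class = "kin_scheme")
}

normalize_roles <- function(roles) {
  if (is.character(roles))
    roles <- lapply(strsplit(roles, ","), function(x) trimws(x[nzchar(trimws(x))]))
  roles <- lapply(roles, function(r) {
    r <- as.character(r %||% character())
    bad <- setdiff(r, kin_roles)
    if (length(bad))
      stop("unknown species role(s): ", paste(bad, collapse = ", "),
           " (expected subset of ", paste(kin_roles, collapse = ", "), ")",
           call. = FALSE)
    r
  })
  roles
}

#' @export
print.kin_scheme <- function(x, ...) {
  cat("<kin_scheme> ", nrow(x$species), " species, ",
      nrow(x$transitions), " transitions\n", sep = "")
  cat("species (uM):\n")
  print(tibble::tibble(
    name = x$species$name, initial = x$species$initial,
    roles = vapply(x$species$roles, paste, "", collapse = ",")))
  cat("transitions:\n")
  fmt <- function(v) paste(ifelse(v > 1, paste0(v, " "), ""), names(v),
                           sep = "", collapse = " + ")
  for (i in seq_len(nrow(x$transitions)))
    cat(sprintf("  %s: %s -> %s  (k = %g)\n", x$transitions$name[i],
                fmt(x$transitions$from[[i]]), fmt(x$transitions$to[[i]]),
                x$transitions$k[i]))
  invisible(x)
}

#' Stoichiometry matrices of a scheme
#'
#' @param scheme A [kin_scheme()].
#' @return List with integer matrices `N_src`, `N_tgt`, `N` (transitions in
#'   rows, species in columns) and the rate-constant vector `k`.
#' @export
stoichiometry <- function(scheme) {
  stopifnot(inherits(scheme, "kin_scheme"))
  scheme[c("N_src", "N_tgt", "N", "k")]
}

#' Conserved moieties of a kinetic scheme
#'
#' Finds species-space vectors v with N v = 0; the corresponding weighted
#' concentration sums (for example total enzyme and total inhibitor) are
#' constant along every trajectory. The null space is computed by exact
#' Gauss-Jordan elimination on the integer stoichiometry matrix, scaled to
#' integer vectors; when possible, basis vectors are recombined into
#' non-negative ones so that each reads directly as a moiety count.
#'
#' @param scheme A [kin_scheme()].
#' @return Integer matrix with one column per conserved moiety (species in
#'   rows), possibly with zero columns. Used for validation and reporting.
#' @examples
#' sch <- build_scheme("scheme2", E0 = 1e-3, I0 = 1, kon = 1e-2, koff = 1e-2,
#'                     kr = 5, knr = 5, kinact = 1e-4)
#' conserved_moieties(sch)
#' @export
conserved_moieties <- function(scheme) {
  stopifnot(inherits(scheme, "kin_scheme"))
  basis <- integer_null_basis(scheme$N)
  if (!ncol(basis)) return(basis)
  nonneg <- nonneg_combinations(basis)
  rownames(nonneg) <- colnames(scheme$N)
  colnames(nonneg) <- paste0("moiety", seq_len(ncol(nonneg)))
  nonneg
}

# Integer basis of {v : M v = 0} via Gauss-Jordan elimination. M has small
# integer entries, so double-precision elimination is exact up to rounding;
# entries are rescaled to the smallest integer representative.
integer_null_basis <- function(M) {
  M <- rbind(M)
  n <- ncol(M)
  A <- matrix(as.numeric(M), nrow(M), n)
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(n)) {
    if (row > nrow(A)) break
    sel <- which.max(abs(A[row:nrow(A), col])) + row - 1L
    if (abs(A[sel, col]) < 1e-9) next
    A[c(row, sel), ] <- A[c(sel, row), ]
    A[row, ] <- A[row, ] / A[row, col]
    for (r in setdiff(seq_len(nrow(A)), row))
      A[r, ] <- A[r, ] - A[r, col] * A[row, ]
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  free <- setdiff(seq_len(n), pivots)
  basis <- matrix(0, n, length(free))
  for (j in seq_along(free)) {
    basis[free[j], j] <- 1
    for (i in seq_along(pivots))
      basis[pivots[i], j] <- -A[i, free[j]]
  }
  if (ncol(basis)) basis <- apply(basis, 2, smallest_integer_vector)
  basis <- rbind(basis)
  storage.mode(basis) <- "integer"
  basis
}

smallest_integer_vector <- function(v) {
  for (den in 1:64) {
    w <- v * den
    if (all(abs(w - round(w)) < 1e-6)) {
      w <- round(w)
      g <- Reduce(gcd2, abs(w[w != 0]))
      if (length(g) && g > 0) w <- w / g
      return(w)
    }
  }
  v
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

# Recombine an integer null basis into non-negative vectors where possible:
# try sign flips, then small integer combinations of basis pairs.
nonneg_combinations <- function(basis) {
  cols <- lapply(seq_len(ncol(basis)), function(j) basis[, j])
  out <- list()
  add <- function(v) {
    v <- smallest_integer_vector(v)
    if (all(v >= 0) && any(v > 0) &&
        !any(vapply(out, function(u) all(u == v), TRUE)))
      out[[length(out) + 1L]] <<- v
  }
  for (v in cols) { add(v); add(-v) }
  if (length(cols) > 1) {
    combos <- expand.grid(rep(list(-2:2), length(cols)))
    for (i in seq_len(nrow(combos))) {
      w <- as.numeric(as.matrix(basis) %*% as.numeric(combos[i, ]))
      if (any(w != 0)) add(w)
    }
  }
  # greedily keep a linearly independent non-negative set, topped up with raw
  # basis vectors if non-negativity is not attainable for every dimension
  keep <- list()
  for (v in c(out, cols)) {
    cand <- do.call(cbind, c(keep, list(v)))
    if (qr(cand)$rank == length(keep) + 1L) keep[[length(keep) + 1L]] <- v
    if (length(keep) == ncol(basis)) break
  }
  m <- do.call(cbind, keep)
  storage.mode(m) <- "integer"
  m
}

# Species indices carrying a role tag.
role_index <- function(scheme, role) {
  which(vapply(scheme$species$roles, function(r) role %in% r, TRUE))
}
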