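#' Residue contact map
#'
#' Binary symmetric matrix with \eqn{C_{ij} = 1} iff beads i and j are within
#' `cutoff` of each other and at least `min_seq_sep` apart in sequence
#' (distance test is inclusive, `<= cutoff`). The diagonal is zero.
#'
#' @param s a [cg_structure()].
#' @param cutoff contact distance cutoff (default 7, the conventional
#'   C-alpha contact radius feeding the elastic-network weight matrix).
#' @param min_seq_sep minimum |i - j| for a pair to be eligible (>= 1).
#' @return a `contact_map`: list with `n`, `entries` (n x n 0/1 matrix),
#'   `cutoff`, `min_seq_sep`.
#' @export
compute_contact_map <- function(s, cutoff = 7, min_seq_sep = 1L) {
  stopifnot_cg(s)
  if (cutoff <= 0) stop("cutoff must be positive")
  if (min_seq_sep < 1L) stop("min_seq_sep must be >= 1")
  n <- n_beads(s)
  if (n < 2L) stop("need at least 2 beads")
  D <- as.matrix(stats::dist(s$coords))
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  entries <- (D <= cutoff & sep >= min_seq_sep) * 1
  diag(entries) <- 0
  dimnames(entries) <- NULL
  structure(list(n = n, entries = entries, cutoff = cutoff,
                 min_seq_sep = as.integer(min_seq_sep)),
            class = "contact_map")
}

#' Graph Laplacian (Kirchhoff matrix) of a contact map
#'
#' \eqn{L_{ii} = } degree of i, \eqn{L_{ij} = -C_{ij}} off the diagonal.
#' Row sums are exactly zero and the matrix is positive semidefinite --
#' the standard elastic-network connectivity operator.
#'
#' @param cm a `contact_map` from [compute_contact_map()].
#' @return n x n numeric Laplacian matrix.
#' @export
laplacian_from_contacts <- function(cm) {
  if (!inherits(cm, "contact_map")) stop("cm must be a contact_map")
  L <- -cm$entries
  diag(L) <- rowSums(cm$entries)
  L
}

#' Chain-connectivity (covalent backbone) Laplacian
#'
#' Path-graph Laplacian for an n-bead chain: tridiagonal with diagonal
#' 1, 2, ..., 2, 1 and off-diagonal -1. Its negative is the system matrix of
#' the overdamped CG equation of motion (up to the spring/friction ratio):
#' all eigenvalues of the negated matrix are negative except one zero, the
#' rigid translation mode.
#'
#' @param n number of beads (>= 2).
#' @return n x n numeric matrix.
#' @export
chain_connectivity <- function(n) {
  if (n < 2L) stop("chain needs at least 2 beads")
  L <- diag(c(1, rep(2, n - 2L), 1))
  idx <- seq_len(n - 1L)
  L[cbind(idx, idx + 1L)] <- -1
  L[cbind(idx + 1L, idx)] <- -1
  L
}

#' LQR state-weight matrix from the current conformation
#'
#' \eqn{Q = L_{nb} + \epsilon I}, where \eqn{L_{nb}} is the contact-map
#' Laplacian excluding covalent (|i - j| = 1) pairs -- those live in the
#' chain-connectivity matrix of the dynamics -- and the \eqn{\epsilon I}
#' ridge makes Q positive definite so the regulator can stabilise the
#' zero (translation) mode. Contacts are taken from the conformation as
#' given, so nonnative contacts present during folding enter Q while they
#' persist; set `native_only` with a reference to restrict Q to contacts
#' also present in that reference (a Go-like filter, off by default).
#'
#' @param s current conformation, a [cg_structure()].
#' @param cutoff contact cutoff for the Laplacian (default 7).
#' @param epsilon positive ridge (default 0.04).
#' @param native_only optional `cg_structure`: keep only contacts also
#'   present in this reference at the same cutoff.
#' @return a `weight_matrix`: list with `Q`, `epsilon`, `n_contacts`
#'   (number of noncovalent edges that entered the Laplacian).
#' @export
build_Q <- function(s, cutoff = 7, epsilon = 0.04, native_only = NULL) {
  if (epsilon <= 0) stop("epsilon must be positive")
  cm <- compute_contact_map(s, cutoff = cutoff, min_seq_sep = 2L)
  if (!is.null(native_only)) {
    ncm <- compute_contact_map(native_only, cutoff = cutoff, min_seq_sep = 2L)
    cm$entries <- cm$entries * ncm$entries
  }
  Q <- laplacian_from_contacts(cm) + diag(epsilon, cm$n)
  structure(list(Q = Q, epsilon = epsilon,
                 n_contacts = sum(cm$entries) / 2),
            class = "weight_matrix")
}

#' Count native-like contacts of a conformation
#'
#' Number of unordered residue pairs separated by at least `min_seq_sep` in
#' sequence with C-alpha distance strictly below `cutoff`. Defaults (6.5,
#' sequence separation > 2) follow the usual folding-progress metric; note
#' this is a different, stricter criterion than the contact map feeding Q.
#'
#' @param s a [cg_structure()].
#' @param cutoff strict distance threshold (default 6.5).
#' @param min_seq_sep minimum |i - j| (default 3, i.e. separation > 2).
#' @return integer count.
#' @export
count_native_like_contacts <- function(s, cutoff = 6.5, min_seq_sep = 3L) {
  stopifnot_cg(s)
  if (cutoff <= 0) stop("cutoff must be positive")
  n <- n_beads(s)
  D <- as.matrix(stats::dist(s$coords))
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  as.integer(sum(D < cutoff & sep >= min_seq_sep) / 2L)
}

#' Dump a contact map as a TSV of (i, j, distance) rows
#'
#' Upper-triangle contacts only, for inspection in external tools.
#'
#' @param s the conformation the map was computed from.
#' @param cm its `contact_map`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_contact_tsv <- function(s, cm, path) {
  D <- as.matrix(stats::dist(s$coords))
  idx <- which(upper.tri(cm$entries) & cm$entries == 1, arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2],
                   distance = D[idx])
  df <- df[order(df$i, df$j), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
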