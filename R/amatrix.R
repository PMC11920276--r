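#' Additive relationship matrix from a pedigree
#'
#' Dense numerator relationship matrix A by the tabular method:
#' `A[i,j] = (A[j,sire_i] + A[j,dam_i]) / 2` for `j < i` and
#' `A[i,i] = 1 + A[sire_i,dam_i] / 2`, processing individuals in
#' topological order.
#'
#' @param ped pedigree with columns `id`, `sire`, `dam` (NA for unknown).
#' @return dense matrix with dimnames = ids (pedigree row order).
#' @export
a_matrix <- function(ped) {
  ped <- as.data.table(ped)
  ord <- pedigree_order(ped)
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  s <- unname(idx[ped$sire]); d <- unname(idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in ord) {
    as_ <- if (!is.na(s[i])) A[, s[i]] else numeric(n)
    ad <- if (!is.na(d[i])) A[, d[i]] else numeric(n)
    row <- (as_ + ad) / 2
    A[i, ] <- row; A[, i] <- row
    A[i, i] <- 1 + (if (!is.na(s[i]) && !is.na(d[i])) A[s[i], d[i]] / 2 else 0)
  }
  A
}

#' Sparse inverse of the additive relationship matrix
#'
#' Henderson's rules without inbreeding adjustment: each individual
#' contributes `b = 1/d` to its own diagonal, `-b/2` to individual-parent
#' cells and `b/4` to parent-parent cells, where `d` is the
#' Mendelian-sampling variance fraction (1 for founders, 3/4 with one known
#' parent, 1/2 with both known). Founders contribute identity blocks.
#'
#' @param ped pedigree with columns `id`, `sire`, `dam`.
#' @return sparse symmetric `Matrix` with dimnames = ids.
#' @export
a_matrix_inverse <- function(ped) {
  ped <- as.data.table(ped)
  pedigree_order(ped)                      # validates acyclicity
  n <- nrow(ped)
  idx <- setNames(seq_len(n), ped$id)
  s <- unname(idx[ped$sire]); d <- unname(idx[ped$dam])
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  for (i in seq_len(n)) {
    par <- c(s[i], d[i]); par <- par[!is.na(par)]
    b <- 1 / (1 - 0.25 * length(par))
    add(i, i, b)
    for (p in par) { add(i, p, -b / 2); add(p, i, -b / 2) }
    if (length(par))
      for (p1 in par) for (p2 in par) add(p1, p2, b / 4)
  }
  Ainv <- sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                       dimnames = list(ped$id, ped$id))
  Matrix::forceSymmetric(Ainv)
}
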