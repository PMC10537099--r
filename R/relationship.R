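#' Numerator relationship matrix from a pedigree
#'
#' Tabular (recursive) construction of the additive relationship matrix A:
#' a_ij = 0.5 (a_{j,sire(i)} + a_{j,dam(i)}) for j < i and
#' a_ii = 1 + 0.5 a_{sire(i),dam(i)}. In the two-generation half-sib design
#' no animal is inbred, so the diagonal is 1, full sibs share 0.5, half sibs
#' 0.25 and parent-offspring 0.5.
#'
#' @param ped a [Pedigree-class] object (parents before offspring).
#' @return dense symmetric n x n matrix.
#' @examples
#' A <- relationshipMatrix(buildHalfSibPedigree(1, 2, 2))
#' @export
relationshipMatrix <- function(ped) {
  n <- nAnimals(ped)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- ped@sire[i]
    d <- ped@dam[i]
    if (s == 0L && d == 0L) {
      A[i, i] <- 1
    } else {
      if (i > 1L) {
        j <- seq_len(i - 1L)
        as_ <- if (s != 0L) A[j, s] else 0
        ad_ <- if (d != 0L) A[j, d] else 0
        aij <- 0.5 * (as_ + ad_)
        A[j, i] <- aij
        A[i, j] <- aij
      }
      A[i, i] <- 1 + if (s != 0L && d != 0L) 0.5 * A[s, d] else 0
    }
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Built directly from the pedigree with Henderson's rules for non-inbred
#' parents: each animal contributes 1/d_i to its own diagonal, -0.5/d_i to the
#' animal-parent cells and 0.25/d_i between its parents, with Mendelian
#' sampling variance d_i = 1 (no parents known), 0.75 (one parent) or 0.5
#' (both parents). Valid for pedigrees whose parents are non-inbred, which is
#' always true in the two-generation design used here.
#'
#' @param ped a [Pedigree-class] object.
#' @return sparse symmetric matrix (`Matrix::dsCMatrix`).
#' @examples
#' ped <- buildHalfSibPedigree(2, 2, 2)
#' max(abs(relationshipInverse(ped) %*% relationshipMatrix(ped) -
#'   diag(nAnimals(ped))))
#' @export
relationshipInverse <- function(ped) {
  n <- nAnimals(ped)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  s <- ped@sire
  d <- ped@dam
  nPar <- (s != 0L) + (d != 0L)
  invd <- c(1, 4 / 3, 2)[nPar + 1L] # 1/d_i
  id <- ped@id
  add(id, id, invd)
  both <- which(nPar == 2L)
  if (length(both)) {
    w <- invd[both]
    add(both, s[both], -0.5 * w); add(s[both], both, -0.5 * w)
    add(both, d[both], -0.5 * w); add(d[both], both, -0.5 * w)
    add(s[both], s[both], 0.25 * w)
    add(d[both], d[both], 0.25 * w)
    add(s[both], d[both], 0.25 * w); add(d[both], s[both], 0.25 * w)
  }
  one <- which(nPar == 1L)
  if (length(one)) {
    p <- ifelse(s[one] != 0L, s[one], d[one])
    w <- invd[one]
    add(one, p, -0.5 * w); add(p, one, -0.5 * w)
    add(p, p, 0.25 * w)
  }
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Matrix::forceSymmetric(M)
}
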