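#' Additive (numerator) relationship matrix
#'
#' Builds the expected additive relationship matrix A over a validated
#' pedigree by the recursive tabular method: for individual i with parents
#' s and d (in pedigree order, parents first),
#' `a_ii = 1 + 0.5 a_sd` and `a_ij = 0.5 (a_js + a_jd)` for any older j,
#' terms for unknown parents contributing zero. The diagonal equals
#' `1 + F_i` where `F_i` is the inbreeding coefficient.
#'
#' @param ped A validated pedigree (`validate_pedigree()`).
#' @return A dense symmetric numeric matrix with dimnames the pedigree ids,
#'   in pedigree order, with attribute `"inbreeding"` holding the named
#'   vector of F coefficients.
#' @seealso [a_inverse()] for the sparse inverse used by the animal model.
#' @export
additive_relationship_matrix <- function(ped) {
  assert_pedigree(ped)
  n <- nrow(ped)
  ids <- ped$id
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row_s <- if (!is.na(s)) A[j, s] else 0
      row_d <- if (!is.na(d)) A[j, d] else 0
      aij <- 0.5 * (row_s + row_d)
      A[j, i] <- aij
      A[i, j] <- aij
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  attr(A, "inbreeding") <- setNames(diag(A) - 1, ids)
  A
}

#' Inbreeding coefficients from a pedigree
#'
#' `F_i = 0.5 a(sire_i, dam_i)`, the additive relationship between the
#' parents halved; zero when either parent is unknown (founders are treated
#' as an unrelated, non-inbred base population).
#'
#' @inheritParams additive_relationship_matrix
#' @return Named numeric vector of F in pedigree order.
#' @export
inbreeding_coefficients <- function(ped) {
  attr(additive_relationship_matrix(ped), "inbreeding")
}

#' Sparse inverse of the additive relationship matrix
#'
#' Assembles A-inverse directly from the pedigree by Henderson's rules with
#' Meuwissen-style adjustment for parental inbreeding, without forming or
#' inverting A. Each individual i contributes `1/d_i` to the mixed-model
#' precision, where `d_i` is the Mendelian sampling variance ratio:
#' `d_i = 0.5 - 0.25 (F_s + F_d)` with both parents known,
#' `0.75 - 0.25 F_p` with one known parent p, and `1` for founders.
#'
#' @inheritParams additive_relationship_matrix
#' @return A sparse symmetric matrix (`Matrix::dsCMatrix`) with dimnames the
#'   pedigree ids; its product with [additive_relationship_matrix()] is the
#'   identity (to numerical precision).
#' @export
a_inverse <- function(ped) {
  assert_pedigree(ped)
  n <- nrow(ped)
  ids <- ped$id
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  Fv <- inbreeding_coefficients(ped)
  f_of <- function(k) if (is.na(k)) 0 else Fv[[k]]

  # triplet accumulation; each individual adds at most 9 entries
  ii <- integer(9L * n); jj <- integer(9L * n); xx <- numeric(9L * n)
  m <- 0L
  add <- function(i, j, v) {
    m <<- m + 1L
    ii[m] <<- i; jj[m] <<- j; xx[m] <<- v
  }
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    n_known <- sum(!is.na(c(s, d)))
    dvar <- if (n_known == 2L) {
      0.5 - 0.25 * (Fv[[s]] + Fv[[d]])
    } else if (n_known == 1L) {
      0.75 - 0.25 * f_of(if (is.na(s)) d else s)
    } else 1
    alpha <- 1 / dvar
    add(i, i, alpha)
    for (p in c(s, d)) {
      if (!is.na(p)) {
        add(i, p, -alpha / 2); add(p, i, -alpha / 2)
        add(p, p, alpha / 4)
      }
    }
    if (!is.na(s) && !is.na(d)) {
      add(s, d, alpha / 4); add(d, s, alpha / 4)
    }
  }
  Ainv <- Matrix::sparseMatrix(i = ii[1:m], j = jj[1:m], x = xx[1:m],
                               dims = c(n, n), dimnames = list(ids, ids))
  as(Matrix::forceSymmetric(Ainv), "symmetricMatrix")
}
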