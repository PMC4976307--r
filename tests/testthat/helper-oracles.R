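# Independent oracles used to check the package's linear-algebra and
# sampling code. Deliberately written as plain recursions / dense algebra,
# sharing no code with the implementation.

# Additive relationship by direct recursion on the kinship definition
# (memoised; O(n^2) pairs, fine for the small pedigrees used in tests).
oracle_relationship <- function(ped) {
  n <- nrow(ped)
  ids <- ped$id
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  memo <- new.env(hash = TRUE)
  rel <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    key <- paste(min(i, j), max(i, j))
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (i == j) {
      1 + 0.5 * rel(si[i], di[i])
    } else {
      # recurse on the younger member (larger pedigree position)
      if (i < j) { k <- j; o <- i } else { k <- i; o <- j }
      0.5 * (rel(o, si[k]) + rel(o, di[k]))
    }
    memo[[key]] <- val
    val
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in i:n) {
    A[i, j] <- A[j, i] <- rel(i, j)
  }
  A
}

# Random valid pedigree: founders plus individuals whose parents are drawn
# from older individuals with role-consistent sexes; some parents unknown.
random_test_pedigree <- function(n, n_founders = max(4L, n %/% 4L),
                                 p_unknown = 0.15) {
  id <- sprintf("i%02d", seq_len(n))
  sex <- sample(c("female", "male"), n, replace = TRUE)
  sex[1:2] <- c("female", "male")  # guarantee both sexes among founders
  sire <- rep(NA_character_, n)
  dam <- rep(NA_character_, n)
  for (i in (n_founders + 1L):n) {
    males <- which(sex[seq_len(i - 1L)] == "male")
    females <- which(sex[seq_len(i - 1L)] == "female")
    if (length(males) && runif(1) > p_unknown) {
      sire[i] <- id[males[sample.int(length(males), 1)]]
    }
    if (length(females) && runif(1) > p_unknown) {
      dam[i] <- id[females[sample.int(length(females), 1)]]
    }
  }
  df <- data.frame(id = id, sire = sire, dam = dam, sex = sex,
                   habitat = sample(c("urban", "rural"), n, replace = TRUE))
  validate_pedigree(df[sample.int(n), ])  # shuffled input exercises sorting
}

# Profile maximum-likelihood h2 on a dense multivariate-normal likelihood:
# y ~ N(X beta, sigma2_P (h2 A + (1 - h2) I)), beta and sigma2_P profiled out.
oracle_grid_mle_h2 <- function(y, X, A, grid = seq(0.01, 0.99, by = 0.01)) {
  n <- length(y)
  ll <- vapply(grid, function(h2) {
    V <- h2 * A + (1 - h2) * diag(n)
    cV <- chol(V)
    logdet <- 2 * sum(log(diag(cV)))
    solveV <- function(b) backsolve(cV, forwardsolve(t(cV), b))
    ViX <- solveV(X)
    beta <- solve(crossprod(X, ViX), crossprod(ViX, y))
    r <- y - X %*% beta
    s2 <- sum(r * solveV(r)) / n
    -0.5 * (n * log(s2) + logdet + n)
  }, numeric(1))
  grid[which.max(ll)]
}

# Analytic HPD interval of a Beta(a, b) density: shortest interval with the
# requested mass, found by minimising width over the lower tail probability.
oracle_beta_hpd <- function(a, b, prob = 0.95) {
  width <- function(p1) qbeta(p1 + prob, a, b) - qbeta(p1, a, b)
  opt <- optimize(width, c(0, 1 - prob))
  c(qbeta(opt$minimum, a, b), qbeta(opt$minimum + prob, a, b))
}

# A tiny hand-checkable pedigree: a founder pair with two full-sib
# offspring whose own offspring is inbred (F = 0.25), plus a half sib
# through a second founder female.
fixture_family_pedigree <- function() {
  validate_pedigree(data.frame(
    id   = c("m1", "f1", "f2", "s1", "s2", "h1", "inb"),
    sire = c(NA, NA, NA, "m1", "m1", "m1", "s1"),
    dam  = c(NA, NA, NA, "f1", "f1", "f2", "s2"),
    sex  = c("male", "female", "female", "male", "female", "male", "unknown"),
    stringsAsFactors = FALSE
  ))
}
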