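# Fixtures and independent oracles used across the suite.

# Two Gaussian clusters separated by d SDs on every informative column.
makeTwoClusterData <- function(n = 20, p = 5, d = 6, nInformative = p,
                               seed = 1) {
  set.seed(seed)
  y <- rep(c(0, 1), length.out = n)
  X <- matrix(rnorm(n * p), n, p)
  for (j in seq_len(nInformative)) X[, j] <- X[, j] + d * y
  colnames(X) <- paste0("V", seq_len(p))
  list(X = X, y = y)
}

# Spec with no group difference anywhere (SF parameters copied from CNT).
nullCohortSpec <- function(seed = 1, nSF = 15, nCNT = 12) {
  spec <- defaultCohortSpec(seed = seed, nSF = nSF, nCNT = nCNT)
  a <- analyteParams(spec)
  a$meanSF <- a$meanCNT
  a$sdSF <- a$sdCNT
  a$discriminant <- FALSE
  CohortSpec(a, nSF = nSF, nCNT = nCNT, seed = as.integer(seed))
}

plantedBiomarkers <- function() {
  a <- analyteParams(defaultCohortSpec())
  sort(a$name[a$discriminant])
}

# Exhaustive concordant/tied pair count: the AUROC definition.
bruteAUROC <- function(truth, scores) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Least-squares fitted values via the normal equations (with intercept).
olsFitted <- function(X, y) {
  Z <- cbind(1, X)
  drop(Z %*% solve(crossprod(Z), crossprod(Z, y)))
}

# Exact two-sided Mann-Whitney p by enumerating all group assignments.
enumerateMWPValue <- function(groupA, groupB) {
  pooled <- c(groupA, groupB)
  nA <- length(groupA)
  uStat <- function(idx) {
    a <- pooled[idx]; b <- pooled[-idx]
    sum(outer(a, b, function(x, y) (x > y) + 0.5 * (x == y)))
  }
  obs <- uStat(seq_len(nA))
  us <- apply(utils::combn(length(pooled), nA), 2, uStat)
  mu <- length(groupA) * length(groupB) / 2
  mean(abs(us - mu) >= abs(obs - mu))
}
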