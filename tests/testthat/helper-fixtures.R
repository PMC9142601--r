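# In-code fixtures shared across test files.

# 2D slice with filled discs at the given centers/radii
discSlice <- function(nr, nc, centers, radii) {
  m <- matrix(0, nr, nc)
  for (k in seq_along(radii)) {
    for (i in seq_len(nr)) {
      dx2 <- (i - centers[[k]][1])^2
      cols <- which(dx2 + (seq_len(nc) - centers[[k]][2])^2 <=
                      radii[k]^2)
      m[i, cols] <- 1
    }
  }
  m
}

# small sphere phantom reused by imaging/handcrafted tests
spherePhantom <- function(radius_mm = 10, seed = 3L) {
  n <- as.integer(2 * radius_mm + 20)
  makePhantom(phantomSpec(shape = c(n, n, n),
                          semiaxes_mm = rep(radius_mm, 3), seed = seed))
}

# exhaustive pair-enumeration AUC oracle (ties count 1/2)
aucByEnumeration <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# ANOVA mean-squares ICC oracle via stats::aov on the long format
iccByAov <- function(m) {
  df <- data.frame(value = as.numeric(m),
                   subject = factor(rep(seq_len(nrow(m)), ncol(m))),
                   rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  tab <- summary(stats::aov(value ~ subject + rater, data = df))[[1]]
  MSR <- tab["subject", "Mean Sq"]
  MSC <- tab["rater", "Mean Sq"]
  MSE <- tab["Residuals", "Mean Sq"]
  n <- nrow(m); k <- ncol(m)
  (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}
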