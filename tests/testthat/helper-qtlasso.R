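# small fixtures built in code

# two chromosomes, sparse markers: cheap end-to-end runs
toy_map <- function() {
  genetic_map(paste0("m", 1:8),
              rep(c("c1", "c2"), each = 4),
              rep(c(0, 20, 40, 60), 2))
}

# one 40 cM chromosome with 5 markers
tiny_map <- function() {
  genetic_map(paste0("t", 1:5), rep("c1", 5), c(0, 10, 20, 30, 40))
}

# the benchmark 6 x 100 cM map
bench_map <- function() backcross_10qtl_spec("binary", 10)$map

# brute-force conditional genotype distribution at a locus given a full
# marker vector, by enumerating the two-state Markov chain over
# (markers + locus) positions on one chromosome.  Codes are class indices.
enum_cond_prob <- function(marker_geno, marker_pos, locus_pos) {
  pos <- sort(unique(c(marker_pos, locus_pos)))
  li <- match(locus_pos, pos)
  midx <- match(marker_pos, pos)
  states <- as.matrix(expand.grid(rep(list(1:2), length(pos))))
  r <- map_distance_to_recomb(diff(pos))
  prob <- apply(states, 1, function(s) {
    p <- 0.5
    for (j in seq_along(r)) p <- p * (if (s[j] == s[j + 1]) 1 - r[j] else r[j])
    p
  })
  ok <- apply(states, 1, function(s) {
    obs <- !is.na(marker_geno)
    all(s[midx[obs]] == marker_geno[obs])
  })
  p2 <- sum(prob[ok & states[, li] == 2]) / sum(prob[ok])
  c(1 - p2, p2)
}

# weighted least-squares oracle: minimizes (1/2n) sum w (z - X b)^2
wls_oracle <- function(X, z, w) {
  solve(crossprod(X, w * X), crossprod(X, w * z))
}

# gradient of the smooth part of the LASSO objective at beta
lasso_gradient <- function(X, z, w, beta) {
  wn <- w / mean(w)
  r <- z - as.vector(X %*% beta)
  -as.vector(crossprod(X, wn * r)) / nrow(X)
}
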