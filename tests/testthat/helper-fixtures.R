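# Shared fixture builders; everything is generated in code.

# Tiny 3-deme alignment with known haplotype structure.
toyAlignment <- function() {
  aln <- c(a1 = "ACGTACGT", a2 = "ACGTACGT", b1 = "ACGAACGT",
           b2 = "ACGAACGT", c1 = "ACGAACTT", c2 = "ACGTACGT")
  dm <- data.frame(sample_id = names(aln),
                   deme = c("F", "F", "S", "S", "A", "A"),
                   stringsAsFactors = FALSE)
  list(alignment = aln, demeMap = dm)
}

# Hand-built 3-tip genealogy in one deme: ((t1:0.1, t2:0.1):0.2, t3:0.3).
threeTipGenealogy <- function() {
  emptyPath <- matrix(numeric(0), 0, 2,
                      dimnames = list(NULL, c("time", "deme")))
  new("Genealogy",
      tipLabels = c("t1", "t2", "t3"), demeLabels = "F",
      parent = c(4L, 4L, 5L, 5L, 0L),
      time = c(0, 0, 0, 0.1, 0.3),
      nodeDeme = rep(1L, 5),
      paths = rep(list(emptyPath), 5))
}

# Single-lineage genealogy for stationary-draw checks.
oneTipGenealogy <- function(label = "s1", deme = "F") {
  new("Genealogy", tipLabels = label, demeLabels = deme,
      parent = 0L, time = 0, nodeDeme = 1L,
      paths = list(matrix(numeric(0), 0, 2)))
}

# Brute-force alignment likelihood by enumerating internal node states.
bruteForceLoglik <- function(gen, alignment, model) {
  aln <- demeflow:::asAlignmentMatrix(alignment)
  aln <- aln[gen@tipLabels, , drop = FALSE]
  eg <- demeflow:::modelEigen(model)
  rc <- demeflow:::rateClasses(model)
  n <- length(gen@tipLabels)
  internals <- (n + 1L):length(gen@parent)
  total <- 0
  for (s in seq_len(ncol(aln))) {
    lik <- 0
    for (k in seq_along(rc$rate)) {
      Ps <- list()
      for (v in seq_along(gen@parent)) {
        if (gen@parent[v] == 0) next
        len <- (gen@time[gen@parent[v]] - gen@time[v]) * rc$rate[k]
        Ps[[v]] <- demeflow:::transitionMatrix(eg, len)
      }
      states <- as.matrix(expand.grid(rep(list(1:4), length(internals))))
      for (r in seq_len(nrow(states))) {
        full <- c(match(aln[, s], c("A", "C", "G", "T")), states[r, ])
        p <- model@freqs[full[length(full)]] # root is the last internal
        for (v in seq_along(gen@parent)) {
          if (gen@parent[v] == 0) next
          p <- p * Ps[[v]][full[gen@parent[v]], full[v]]
        }
        lik <- lik + rc$prob[k] * p
      }
    }
    total <- total + log(lik)
  }
  total
}

# Independent level-wise minimal-connection network: returns the component
# label and pairwise connection distance of the sampled haplotypes, built
# from scratch with base R (no igraph).
bruteForceNetwork <- function(seqs, limit) {
  nh <- length(seqs)
  m <- do.call(rbind, strsplit(seqs, ""))
  d <- matrix(0L, nh, nh)
  if (nh > 1)
    for (i in 1:(nh - 1)) for (j in (i + 1):nh)
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
  comp <- seq_len(nh)
  dist <- matrix(Inf, nh, nh)
  diag(dist) <- 0
  for (lv in seq_len(limit)) {
    compAtLevel <- comp
    for (i in seq_len(nh)) for (j in seq_len(nh)) {
      if (i >= j || d[i, j] != lv) next
      if (compAtLevel[i] == compAtLevel[j]) next
      dist[i, j] <- dist[j, i] <- lv
      comp[comp == comp[j]] <- comp[i]
    }
  }
  ## all-pairs shortest paths over the realized direct connections
  for (k in seq_len(nh)) for (i in seq_len(nh)) for (j in seq_len(nh))
    if (dist[i, k] + dist[k, j] < dist[i, j])
      dist[i, j] <- dist[i, k] + dist[k, j]
  list(comp = match(comp, unique(comp)), dist = dist)
}
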