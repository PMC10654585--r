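test_that("K2P distance evaluates the closed form and handles degeneracy", {
  ## identical sequences
  id <- k2p_distance("ACGTACGTAC", "ACGTACGTAC")
  expect_equal(id$P, 0)
  expect_equal(id$Q, 0)
  expect_equal(id$d, 0)

  ## 20 sites, 2 transitions, 1 transversion: P = 0.10, Q = 0.05
  a <- paste(rep("A", 20), collapse = "")
  b <- paste(c("G", "G", "C", rep("A", 17)), collapse = "")
  pd <- k2p_distance(a, b)
  expect_equal(pd$P, 0.10)
  expect_equal(pd$Q, 0.05)
  expect_equal(pd$d, -0.5 * log(0.75) - 0.25 * log(0.9))
  expect_equal(pd$d, 0.170181, tolerance = 1e-6)

  ## saturation: P = 0.40, Q = 0.25 makes 1 - 2P - Q negative
  a <- paste(rep("A", 20), collapse = "")
  b <- paste(c(rep("G", 8), rep("C", 5), rep("A", 7)), collapse = "")
  expect_error(k2p_distance(a, b), class = "hostspec_saturation_error")

  ## gap/N sites are excluded pairwise; all-gap overlap is an error
  pd <- k2p_distance("AC-TN", "ACGTA")
  expect_equal(pd$n_sites, 3)
  expect_error(k2p_distance("---", "ACG"), class = "hostspec_no_overlap_error")
})

test_that("our K2P agrees with the reference implementation in ape", {
  set.seed(21)
  for (i in 1:20) {
    pair <- simulate_k2p_pair(runif(1, 0.01, 0.2), runif(1, 0.5, 4),
                              600, seed = i)
    ours <- k2p_distance(pair["seq_a"], pair["seq_b"])$d
    mat <- rbind(strsplit(pair[["seq_a"]], "")[[1]],
                 strsplit(pair[["seq_b"]], "")[[1]])
    ref <- as.numeric(ape::dist.dna(ape::as.DNAbin(mat), model = "K80",
                                    pairwise.deletion = TRUE))
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("K2P approaches the p-distance for small divergence", {
  ## with P = Q/2 both logs are small; d -> p as p -> 0 (first order)
  n <- 3000
  for (p in c(0.003, 0.001)) {
    n_ts <- round(p * n / 3)           # P = Q/2 with tiny counts
    n_tv <- 2 * n_ts
    a <- paste(rep("A", n), collapse = "")
    b <- paste(c(rep("G", n_ts), rep("C", n_tv), rep("A", n - n_ts - n_tv)),
               collapse = "")
    pd <- k2p_distance(a, b)
    pdist <- (n_ts + n_tv) / n
    ## d = p + O(p^2): relative deviation shrinks with p
    expect_equal(pd$d, pdist, tolerance = 2 * pdist)
  }
})

test_that("the gene-flow rule is inclusive at the threshold", {
  expect_equal(gene_flow_call(0.002), "ongoing_gene_flow")
  expect_equal(gene_flow_call(0.095), "isolated")
  expect_equal(gene_flow_call(0.05), "ongoing_gene_flow")
  expect_equal(gene_flow_call(0.050001), "isolated")
  expect_equal(gene_flow_call(0.036), "ongoing_gene_flow")
  expect_error(gene_flow_call(-0.1), class = "hostspec_validation_error")
})

test_that("barcode-gap delimitation separates two species, lumps clones", {
  ## the two-population configuration: within 0.2-0.3%, between 5.5%
  m <- matrix(c(0, 0.002, 0.055, 0.055,
                0.002, 0, 0.056, 0.055,
                0.055, 0.056, 0, 0.003,
                0.055, 0.055, 0.003, 0), 4, 4,
              dimnames = rep(list(c("Pm1", "Pm2", "Pa1", "Pa2")), 2))
  part <- delimit_otus(m)
  expect_equal(length(part$clusters), 2)
  expect_setequal(part$clusters[[1]], c("Pm1", "Pm2"))
  expect_setequal(part$clusters[[2]], c("Pa1", "Pa2"))
  expect_gt(part$gap_width, 0.05)

  ## all-zero matrix collapses to one cluster
  z <- matrix(0, 3, 3, dimnames = rep(list(letters[1:3]), 2))
  expect_equal(length(delimit_otus(z)$clusters), 1)

  ## singleton matrix: one cluster, gap undefined, no error
  s <- matrix(0, 1, 1, dimnames = list("a", "a"))
  p1 <- delimit_otus(s)
  expect_equal(length(p1$clusters), 1)
  expect_true(is.na(p1$gap_width))
})

test_that("two-blob matrices always resolve to exactly two clusters", {
  set.seed(33)
  for (i in 1:100) {
    n1 <- sample(2:4, 1); n2 <- sample(2:4, 1); n <- n1 + n2
    m <- matrix(runif(n * n, 0.08, 0.15), n, n)
    m[seq_len(n1), seq_len(n1)] <- runif(n1 * n1, 0, 0.01)
    m[n1 + seq_len(n2), n1 + seq_len(n2)] <- runif(n2 * n2, 0, 0.01)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 0
    rownames(m) <- colnames(m) <- paste0("x", seq_len(n))
    part <- delimit_otus(m, threshold_grid = seq(0.005, 0.12, by = 0.005))
    expect_equal(length(part$clusters), 2)
    ## oracle: connected components of the thresholded graph
    memb <- components_oracle(m, part$threshold_used)
    expect_equal(length(unique(memb)), 2)
    expect_equal(split(rownames(m), memb),
                 split(unlist(part$clusters),
                       rep(seq_along(part$clusters),
                           lengths(part$clusters))),
                 ignore_attr = TRUE)
  }
})

test_that("distance matrices stay symmetric under label permutation", {
  pair1 <- simulate_k2p_pair(0.05, 2, 400, seed = 5)
  pair2 <- simulate_k2p_pair(0.1, 2, seed = 6, ancestor = pair1["seq_a"])
  seqs <- c(a = unname(pair1["seq_a"]), b = unname(pair1["seq_b"]),
            c = unname(pair2["seq_b"]))
  m <- k2p_matrix(seqs)
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 0))
  perm <- c("c", "a", "b")
  m2 <- k2p_matrix(seqs[perm])
  expect_equal(m2, m[perm, perm])
})
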