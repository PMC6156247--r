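test_that("flooring replaces non-positive signals by one", {
  m <- matrix(c(-3, 0, 5, 2, -1, 7), ncol = 2)
  f <- floor_negatives(m)
  expect_equal(as.numeric(f), c(1, 1, 5, 2, 1, 7))

  pos <- matrix(c(2, 3, 4, 5), ncol = 2)
  expect_equal(floor_negatives(pos), pos)
  expect_equal(floor_negatives(-pos), matrix(1, 2, 2))
})

test_that("log transform is base-2 and guards against non-positives", {
  m <- matrix(c(1, 8, 2, 1024), ncol = 2)
  expect_equal(log_transform(m), matrix(c(0, 3, 1, 10), ncol = 2))
  expect_error(log_transform(matrix(c(0, 1), ncol = 1)),
               "floor_negatives")
})

test_that("background subtraction removes the per-sample 5th percentile", {
  const <- matrix(5, nrow = 4, ncol = 2)
  expect_equal(subtract_background(const), matrix(0, 4, 2))

  m <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 2)
  # hand oracle: per-column 5th percentile of 3 values (type-7 quantile)
  off <- apply(m, 2, function(v) sort(v)[1] + 0.1 * diff(sort(v))[1])
  expected <- pmax(sweep(m, 2, off), 0)
  expect_equal(subtract_background(m), expected)

  expect_equal(subtract_background(m, method = "none"), m)
})

test_that("quantile normalization matches the hand-computed rank means", {
  m <- matrix(c(1, 2, 3, 2, 4, 6), ncol = 2)
  q <- quantile_normalize(m)
  expect_equal(q[, 1], c(1.5, 3.0, 4.5))
  expect_equal(q[, 2], c(1.5, 3.0, 4.5))

  # fixed point on identical samples
  same <- matrix(c(5, 1, 7, 5, 1, 7), ncol = 2)
  expect_equal(quantile_normalize(same), same)

  # permuting rows of one sample leaves its value multiset unchanged
  set.seed(1)
  a <- rnorm(50); b <- rnorm(50)
  q1 <- quantile_normalize(cbind(a, b))
  q2 <- quantile_normalize(cbind(a, b[sample(50)]))
  expect_equal(sort(q2[, 2]), sort(q1[, 2]))

  expect_warning(one <- quantile_normalize(matrix(1:3, ncol = 1)),
                 "2 samples")
  expect_equal(one, matrix(1:3, ncol = 1))
})

test_that("after quantile normalization all samples share one distribution", {
  set.seed(42)
  m <- matrix(rlnorm(500 * 4, 5, 1), ncol = 4)
  q <- quantile_normalize(m)
  s <- apply(q, 2, sort)
  for (j in 2:4) expect_equal(s[, j], s[, 1], tolerance = 1e-9)
  expect_equal(mean(q), mean(m), tolerance = 1e-9)
})

make_es <- function(vals, conds) {
  colnames(vals) <- unlist(lapply(unique(conds), function(u)
    paste0(u, ".", seq_len(sum(conds == u)))))
  rownames(vals) <- sprintf("g%02d", seq_len(nrow(vals)))
  expr_set(vals)
}

test_that("replicate_test computes linear FC and a Welch p per gene", {
  # identical replicates across conditions: FC 1, p 1
  vals <- matrix(c(5, 6, 5, 6, 5, 6, 5, 6), nrow = 2)
  es <- make_es(vals, c("a", "a", "b", "b"))
  r <- replicate_test(es, "a", "b")
  expect_equal(r$mean_fc, c(1, 1))
  expect_equal(r$p_value, c(1, 1))

  # exact +1 log2 shift with zero within-condition variance: FC 2
  vals2 <- matrix(c(5, 5, 6, 6), nrow = 1)
  es2 <- make_es(vals2, c("a", "a", "b", "b"))
  r2 <- replicate_test(es2, "a", "b")
  expect_equal(r2$mean_fc, 2)
  expect_equal(r2$p_value, 0)

  # textbook Welch oracle on a 2+2 toy
  a <- c(5.0, 5.4); b <- c(7.1, 6.5)
  es3 <- make_es(matrix(c(a, b), nrow = 1), c("a", "a", "b", "b"))
  r3 <- replicate_test(es3, "a", "b")
  tt <- t.test(b, a)
  expect_equal(r3$p_value, tt$p.value)
  expect_equal(r3$mean_fc, 2^(mean(b) - mean(a)))

  # pooled-variance switch equals the classical equal-variance test
  r4 <- replicate_test(es3, "a", "b", var = "pooled")
  expect_equal(r4$p_value, t.test(b, a, var.equal = TRUE)$p.value)

  expect_error(replicate_test(make_es(matrix(1:4, 1), c("a", "a", "a", "b")),
                              "a", "b"), "replicates")
})

test_that("induction filter applies inclusive fc and p thresholds", {
  calls <- data.frame(gene_id = c("a", "b", "c", "d"),
                      gene_name = c("a", "b", "c", "d"),
                      mean_fc = c(2.0, 9298.61, 1.99, 3),
                      p_value = c(0.05, 0.001, 0.01, 0.2))
  kept <- induced_genes(calls)
  expect_setequal(kept$gene_id, c("a", "b"))
})

test_that("the FC-ratio inhibition criterion is inclusive at 4", {
  r <- inhibition_call(9298.61, 615.79)
  expect_equal(r$ratio, 9298.61 / 615.79, tolerance = 1e-12)
  expect_true(r$inhibited)
  expect_equal(round(r$ratio, 2), 15.10)

  expect_true(inhibition_call(100, 25)$inhibited)   # exactly 4
  expect_false(inhibition_call(100, 26)$inhibited)  # ~3.85
  expect_error(inhibition_call(10, 0), "positive")
})

test_that("raising the stimulated FC never turns an inhibited call off", {
  set.seed(3)
  for (i in 1:50) {
    fc_inh <- runif(1, 0.1, 50)
    fc1 <- runif(1, 0.1, 500)
    fc2 <- fc1 + runif(1, 0, 500)
    c1 <- inhibition_call(fc1, fc_inh)$inhibited
    c2 <- inhibition_call(fc2, fc_inh)$inhibited
    expect_true(!c1 || c2)
  }
})

test_that("Venn regions are exhaustive and sum to the union", {
  out <- common_inhibited(list(A = c("g1", "g2"), B = "g2",
                               C = c("g2", "g3")))
  expect_equal(out$regions[["A"]], 1)      # g1
  expect_equal(out$regions[["C"]], 1)      # g3
  expect_equal(out$regions[["A&B&C"]], 1)  # g2
  expect_equal(sum(out$regions), out$union_size)
  expect_equal(out$intersection$gene_id, "g2")
  expect_equal(length(out$regions), 2^3 - 1)

  disj <- common_inhibited(list(A = "x", B = "y"))
  expect_equal(nrow(disj$intersection), 0)
})

test_that("Venn counts match a brute-force region enumeration", {
  set.seed(9)
  pool <- sprintf("g%03d", 1:40)
  for (i in 1:10) {
    sets <- list(A = sample(pool, 15), B = sample(pool, 20),
                 C = sample(pool, 10))
    out <- common_inhibited(sets)
    union <- unique(unlist(sets))
    for (nm in names(out$regions)) {
      inset <- strsplit(nm, "&")[[1]]
      outset <- setdiff(names(sets), inset)
      want <- sum(vapply(union, function(g)
        all(vapply(inset, function(s) g %in% sets[[s]], logical(1))) &&
          !any(vapply(outset, function(s) g %in% sets[[s]], logical(1))),
        logical(1)))
      expect_equal(unname(out$regions[nm]), want)
    }
    expect_equal(sum(out$regions), length(union))
  }
})

test_that("conflicting id/name pairings are an integrity error", {
  a <- data.frame(gene_id = "g1", gene_name = "CXCL10")
  b <- data.frame(gene_id = "g1", gene_name = "CXCL9")
  expect_error(common_inhibited(list(A = a, B = b)), "gene_name")
})

test_that("analyze_expression chains the pipeline end to end", {
  sim <- simulate_expression(n_genes = 200, noise_sd = 0.05,
                             p_negative = 0, seed = 21)
  an <- analyze_expression(sim$es, sim$design, var = "pooled")
  tr <- sim$truth
  expect_equal(an$calls$induced, tr$induced)
  for (inh in c("C01L_F03", "STATTIC", "STX0119"))
    expect_equal(an$calls[[paste0("inhibited_", inh)]],
                 tr[[paste0("inhibited_", inh)]])
  expect_equal(sum(an$venn$regions), an$venn$union_size)
})
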