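test_that("delta-Ct is the target-minus-reference cycle difference", {
  expect_equal(delta_ct(25.0, 20.0), 5.0)
  expect_equal(delta_ct(20.0, 20.0), 0.0)
  expect_equal(delta_ct(c(25, 26), 20), c(5, 6))
})

test_that("delta-Ct is computed per replicate, not on group means", {
  set.seed(14)
  ct <- simulate_qpcr(data.frame(gene = "g1", group = c("a", "b"),
                                 fold = c(1, 1.5)),
                      replicates = 4, noise_sd = 0.3, seed = 14)
  dct <- delta_ct_table(ct)
  # replicate-wise contract: each row equals its own well pair difference
  for (i in seq_len(nrow(dct))) {
    tgt <- ct$ct[ct$gene == "g1" & ct$sample == dct$sample[i] &
                   ct$replicate == dct$replicate[i]]
    ref <- ct$ct[ct$gene == "HPRT" & ct$sample == dct$sample[i] &
                   ct$replicate == dct$replicate[i]]
    expect_equal(dct$delta_ct[i], tgt - ref)
  }
  # and differs in general from the mean-wise shortcut at replicate level
  expect_gt(var(dct$delta_ct), 0)
})

test_that("missing reference wells are reported by sample", {
  ct <- data.frame(sample = c("a_1", "a_1"), group = "a",
                   gene = c("g1", "HPRT"), replicate = c(1, 1),
                   ct = c(25, 20))
  ct2 <- rbind(ct, data.frame(sample = "a_2", group = "a", gene = "g1",
                              replicate = 1, ct = 24))
  expect_error(delta_ct_table(ct2), "a_2")
  expect_error(delta_ct_table(ct[1, ]), "reference")
})

test_that("fold change follows the 2^-ddCt identities", {
  expect_equal(fold_change(5, 5)$fold, 1.0)         # ddCt 0 -> fold 1
  expect_equal(fold_change(4, 5)$fold, 2.0)         # ddCt -1 -> fold 2
  expect_equal(fold_change(5 + 1.1203, 5)$fold, 0.46, tolerance = 0.01)
  # antisymmetry: swapping groups inverts the fold exactly
  set.seed(6)
  a <- rnorm(6, 4); b <- rnorm(6, 5)
  expect_equal(fold_change(a, b)$fold * fold_change(b, a)$fold, 1.0)
})

test_that("folds are invariant to per-sample Ct offsets", {
  d <- data.frame(gene = rep(c("g1", "g2"), each = 2),
                  group = rep(c("control", "dex"), 2),
                  fold = c(1, 2, 1, 0.5))
  ct <- simulate_qpcr(d, replicates = 4, noise_sd = 0.1, seed = 10)
  shifted <- ct
  off <- setNames(rnorm(length(unique(ct$sample)), 0, 3), unique(ct$sample))
  shifted$ct <- ct$ct + off[shifted$sample]
  f1 <- fold_change_table(ct, "dex", "control")
  f2 <- fold_change_table(shifted, "dex", "control")
  expect_equal(f1$fold, f2$fold)
  expect_equal(f1$p_value, f2$p_value)
})

test_that("two-group comparison matches the hand-computed pooled t", {
  x <- c(4.1, 4.5, 3.9, 4.3) # fixed delta-Ct vectors
  y <- c(5.0, 5.4, 5.2, 4.8)
  fc <- fold_change(x, y)
  sp <- sqrt(((4 - 1) * var(x) + (4 - 1) * var(y)) / (4 + 4 - 2))
  t_stat <- (mean(x) - mean(y)) / (sp * sqrt(1 / 4 + 1 / 4))
  p_hand <- 2 * pt(-abs(t_stat), df = 6)
  expect_equal(fc$p_value, p_hand, tolerance = 1e-12)

  # identical groups: t = 0, p = 1
  expect_equal(fold_change(x, x)$p_value, 1)
})

test_that("k-group comparison runs ANOVA with gated Bonferroni post hoc", {
  set.seed(20)
  d <- data.frame(gene = "g1",
                  group = rep(c("control", "dex", "siRNA"), each = 2),
                  fold = c(1, 1, 4, 4, 0.25, 0.25))[c(1, 3, 5), ]
  ct <- simulate_qpcr(d, replicates = 5, noise_sd = 0.15, seed = 20)
  res <- compare_groups(ct)
  expect_equal(res$per_gene$test, "anova")
  expect_lt(res$per_gene$p_value, 0.05)
  expect_false(is.null(res$pairwise))
  expect_true(all(res$pairwise$p_adjusted <= 1))

  # ANOVA p equals the hand-computed F tail on the same delta-Ct values
  dct <- delta_ct_table(ct)
  gm <- tapply(dct$delta_ct, dct$group, mean)
  ssb <- sum(tapply(dct$delta_ct, dct$group,
                    function(v) length(v) * (mean(v) - mean(dct$delta_ct))^2))
  ssw <- sum(tapply(dct$delta_ct, dct$group,
                    function(v) sum((v - mean(v))^2)))
  f_hand <- (ssb / 2) / (ssw / (nrow(dct) - 3))
  expect_equal(res$per_gene$p_value,
               pf(f_hand, 2, nrow(dct) - 3, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("gated Bonferroni pairwise tests keep null error at or below alpha", {
  set.seed(77)
  d <- data.frame(gene = "g1", group = c("a", "b", "c"), fold = 1)
  hits <- 0; nrep <- 400
  for (i in 1:nrep) {
    ct <- simulate_qpcr(d, replicates = 4, noise_sd = 0.3, seed = 1e6 + i)
    res <- compare_groups(ct)
    if (!is.null(res$pairwise) && any(res$pairwise$p_adjusted < 0.05))
      hits <- hits + 1
  }
  # family-wise error of the gated procedure must not exceed alpha
  expect_lte(hits, qbinom(0.995, nrep, 0.05))
})

test_that("configured folds are recovered from noisy plates", {
  folds <- c(0.46, 0.7, 1.4, 3)
  d <- rbind(data.frame(gene = paste0("g", seq_along(folds)),
                        group = "control", fold = 1),
             data.frame(gene = paste0("g", seq_along(folds)),
                        group = "dex", fold = folds))
  # average over replicated plates, as the assay is run in practice
  est <- sapply(1:8, function(i) {
    ct <- simulate_qpcr(d, replicates = 6, noise_sd = 0.2, seed = 100 + i)
    res <- fold_change_table(ct, "dex", "control")
    res$fold[match(paste0("g", seq_along(folds)), res$gene)]
  })
  recovered <- 2^rowMeans(log2(est))
  expect_true(all(abs(recovered / folds - 1) < 0.15))
})

test_that("concordance scores methylation and expression directions", {
  folds <- data.frame(gene = c("Txnip", "Cyba", "down", "flat", "lonely"),
                      fold = c(1.8, 1.6, 0.5, 1.7, 2.0))
  status <- data.frame(
    gene = c("Txnip", "Cyba", "down", "flat", "orphan"),
    status = c("hypomethylated_in_dex", "hypermethylated_in_dex",
               "hypermethylated_in_dex", "unchanged",
               "hypomethylated_in_dex"))
  rep <- concordance_report(folds, status)
  get <- function(g, col) rep[[col]][rep$gene == g]
  expect_true(get("Txnip", "concordant"))    # hypo + up
  expect_false(get("Cyba", "concordant"))    # hyper + up: discordant
  expect_true(get("down", "concordant"))     # hyper + down
  expect_false(get("flat", "scored"))        # unchanged: unscored
  expect_false(get("lonely", "scored"))      # no methylation call
  expect_false(get("orphan", "scored"))      # no expression measurement
  expect_equal(attr(rep, "concordant_fraction"), 2 / 3)
})

test_that("Ct tables round-trip through TSV and are validated", {
  d <- data.frame(gene = "g1", group = c("a", "b"), fold = c(1, 2))
  ct <- simulate_qpcr(d, replicates = 3, noise_sd = 0.1, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ct_table(ct, path)
  back <- read_ct_table(path)
  expect_equal(back$ct, ct$ct, tolerance = 1e-9)
  bad <- ct; bad$ct[1] <- -1
  expect_error(write_ct_table(bad, path), "positive")
})
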