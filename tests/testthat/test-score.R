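test_that("z-transformation hits mean 0 / variance 1 to 1e-10", {
  mat <- tibble::tibble(feature = c("f1", "f2"),
                        P1 = c(1, 10), P2 = c(2, 20), P3 = c(3, 40))
  z <- zscore_matrix(mat)
  expect_equal(as.numeric(z[1, -1]), c(-1, 0, 1))
  x <- as.matrix(dplyr::select(z, -feature))
  expect_true(all(abs(rowMeans(x)) < 1e-10))
  expect_true(all(abs(apply(x, 1, var) - 1) < 1e-10))

  set.seed(3)
  big <- dplyr::bind_cols(
    tibble::tibble(feature = sprintf("f%d", 1:50)),
    tibble::as_tibble(matrix(rnorm(50 * 30) * 7 + 2, 50,
                             dimnames = list(NULL, sprintf("P%d", 1:30))))
  )
  zb <- as.matrix(dplyr::select(zscore_matrix(big), -feature))
  expect_true(all(abs(rowMeans(zb)) < 1e-10))
  expect_true(all(abs(apply(zb, 1, var) - 1) < 1e-10))

  expect_warning(z2 <- zscore_matrix(
    dplyr::bind_rows(mat, tibble::tibble(feature = "flat", P1 = 5, P2 = 5,
                                         P3 = 5))), "zero-variance")
  expect_false("flat" %in% z2$feature)
  expect_error(zscore_matrix(mat["feature"]), ">= 2 patients|feature")
})

test_that("combined score applies the -1 weighting over all members", {
  z <- tibble::tibble(feature = c("u1", "u2", "d1"),
                      P1 = c(1.0, 0.5, -0.5), P2 = c(0, 0, 0))
  sig <- tibble::tibble(gene_id = c("u1", "u2", "d1"),
                        direction = c("up", "up", "down"))
  sc <- signature_score(z, sig)
  # (1.0 + 0.5 - (-0.5)) / 3
  expect_equal(sc$combined_score[1], 2 / 3, tolerance = 1e-15)
  expect_equal(sc$up_score[1], 0.75)
  expect_equal(sc$down_score[1], -0.5)

  # an empty down set collapses the combined score onto the up mean
  sig_up <- sig[sig$direction == "up", ]
  sc_up <- signature_score(z, sig_up)
  expect_equal(sc_up$combined_score, sc_up$up_score)

  # negating a down gene and relabeling it up leaves the score unchanged
  z_flip <- z; z_flip[3, -1] <- -z_flip[3, -1]
  sig_flip <- tibble::tibble(gene_id = c("u1", "u2", "d1"),
                             direction = "up")
  expect_equal(signature_score(z_flip, sig_flip)$combined_score,
               sc$combined_score)

  # scaling all z-values scales every score linearly
  z_scaled <- dplyr::mutate(z, dplyr::across(-feature, ~ .x * 3))
  expect_equal(signature_score(z_scaled, sig)$combined_score,
               3 * sc$combined_score)

  expect_message(
    signature_score(z, dplyr::bind_rows(
      sig, tibble::tibble(gene_id = "absent", direction = "up"))),
    "absent")
  expect_error(
    signature_score(z, tibble::tibble(gene_id = "nope", direction = "up")),
    "no gene")
})

test_that("median dichotomization sends ties low and swaps under negation", {
  sc <- tibble::tibble(patient_id = sprintf("P%d", 1:100),
                       combined_score = 1:100)
  g <- dichotomize_median(sc)
  expect_equal(sum(g$group == "high"), 50L)
  expect_equal(sum(g$group == "low"), 50L)

  tied <- tibble::tibble(patient_id = c("a", "b", "c", "d"),
                         combined_score = c(1, 2, 2, 3))
  gt <- dichotomize_median(tied)
  expect_equal(gt$group, c("low", "low", "low", "high"))

  neg <- dichotomize_median(dplyr::mutate(sc, combined_score =
                                            -combined_score))
  expect_equal(neg$group == "high", g$group == "low")

  expect_error(dichotomize_median(
    tibble::tibble(patient_id = c("a", "b"), combined_score = c(1, 1))),
    "identical")
})

test_that("quartile stratification keeps the strict outer tails", {
  sc <- tibble::tibble(patient_id = sprintf("P%d", 1:100),
                       combined_score = 1:100)
  q <- quartile_stratify(sc)
  # type-7 percentiles of 1..100 are 25.75 and 75.25
  expect_setequal(q$patient_id[q$group == "low"], sprintf("P%d", 1:25))
  expect_setequal(q$patient_id[q$group == "high"], sprintf("P%d", 76:100))
  expect_equal(sum(q$group == "excluded"), 50L)

  # rank invariance under a strictly increasing transform
  q2 <- quartile_stratify(dplyr::mutate(sc, combined_score =
                                          exp(combined_score / 10)))
  expect_equal(q$group, q2$group)

  expect_error(quartile_stratify(sc[1:5, ]), ">= 8")
  expect_error(quartile_stratify(
    dplyr::mutate(sc, combined_score = 1)), "identical")
})

test_that("covariate association is a tie-aware Spearman correlation", {
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  expect_equal(covariate_association(x, x)$rho, 1)
  expect_equal(covariate_association(x, -x)$rho, -1)
  set.seed(13)
  a <- rnorm(1000); b <- sample(a)
  expect_lt(abs(covariate_association(a, b)$rho), 0.08)
  expect_error(covariate_association(rep(1, 10), rnorm(10)), "constant")
  expect_error(covariate_association(1:3, 3:1), ">= 5")
})
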