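test_that("promoter/body assignment follows the TSS window definitions", {
  ann <- tiny_annotation()
  site <- function(pos, chrom = "chr1") {
    assign_regions(tibble::tibble(chrom = chrom, pos = pos), ann)
  }
  # plus-strand gene, TSS = 1000
  expect_equal(site(1200L)$region, "promoter")
  expect_equal(site(500L)$region, "promoter")     # TSS - 500
  expect_equal(site(1500L)$region, "promoter")    # boundary base: promoter only
  expect_equal(site(1501L)$region, "body")        # first body base
  expect_equal(site(5000L)$region, "body")        # terminus inclusive
  expect_equal(nrow(site(5001L)), 0L)
  # minus-strand gene, TSS = tx_end = 12000
  expect_equal(site(12400L)$region, "promoter")
  expect_equal(site(11500L)$region, "promoter")   # TSS - 500 (oriented)
  expect_equal(site(11499L)$region, "body")
  expect_equal(site(8000L)$region, "body")
  # far away on a chromosome with no gene in range
  expect_equal(nrow(site(1e7L, "chr2")), 0L)
})

test_that("assignment matches the linear-scan oracle on random annotations", {
  set.seed(19)
  for (rep in 1:10) {
    n <- 6
    starts <- sort(sample(2000:50000, n))
    ann <- validate_ann_tbl(tibble::tibble(
      gene_id = sprintf("g%d", 1:n),
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      strand = sample(c("+", "-"), n, replace = TRUE),
      tx_start = starts,
      tx_end = starts + sample(1500:4000, n)
    ))
    sites <- tibble::tibble(
      chrom = sample(c("chr1", "chr2"), 60, replace = TRUE),
      pos = sample(1000:60000, 60)
    )
    got <- assign_regions(sites, ann)
    want <- dplyr::bind_rows(purrr::map(seq_len(nrow(sites)), function(i) {
      hits <- oracle_assign(sites$chrom[i], sites$pos[i], ann)
      if (nrow(hits) == 0) return(NULL)
      dplyr::mutate(hits, chrom = sites$chrom[i], pos = sites$pos[i],
                    .before = 1)
    }))
    if (is.null(want) || nrow(want) == 0) {
      expect_equal(nrow(got), 0L)
    } else {
      want <- dplyr::arrange(want, chrom, pos, gene_id, region)
      expect_equal(got[c("chrom", "pos", "gene_id", "region")],
                   want[c("chrom", "pos", "gene_id", "region")])
    }
  }
})

test_that("mirroring a gene to the minus strand mirrors its assignments", {
  ann_plus <- validate_ann_tbl(tibble::tibble(
    gene_id = "g", chrom = "c", strand = "+",
    tx_start = 10000L, tx_end = 14000L
  ))
  # reflect coordinates around M: x -> 2M - x
  M <- 12000L
  ann_minus <- validate_ann_tbl(tibble::tibble(
    gene_id = "g", chrom = "c", strand = "-",
    tx_start = 2L * M - 14000L, tx_end = 2L * M - 10000L
  ))
  pos <- seq(9000L, 15000L, by = 7L)
  a_plus <- assign_regions(tibble::tibble(chrom = "c", pos = pos), ann_plus)
  a_minus <- assign_regions(tibble::tibble(chrom = "c",
                                           pos = 2L * M - pos), ann_minus)
  key_plus <- paste(a_plus$pos, a_plus$region)
  key_minus <- paste(2L * M - a_minus$pos, a_minus$region)
  expect_setequal(key_plus, key_minus)
})

test_that("region calls require min_cpgs DMCs and summarize their members", {
  ann <- tiny_annotation()
  dmc_tbl <- function(pos, diffs, is_dmc = TRUE) {
    tibble::tibble(chrom = "chr1", pos = pos, strand = "+",
                   meth_diff = diffs, p_raw = 1e-6, q_value = 1e-5,
                   is_dmc = is_dmc)
  }
  # three DMCs in geneA's promoter: call emitted
  d3 <- dmc_tbl(c(700L, 900L, 1300L), c(30, 40, -26))
  calls <- call_region_dm(d3, ann)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$n_dmc, 3L)
  expect_equal(calls$meth_diff_summary, mean(c(30, 40, -26)),
               tolerance = 1e-12)
  expect_equal(round(calls$meth_diff_summary, 2), 14.67)
  expect_equal(calls$direction, "hyper")
  expect_true(calls$discordant)

  # two DMCs only: no call
  d2 <- dmc_tbl(c(700L, 900L), c(30, 40))
  expect_equal(nrow(call_region_dm(d2, ann)), 0L)

  # counting tested CpGs instead of DMCs is available behind the flag
  d_mixed <- dmc_tbl(c(700L, 900L, 1300L), c(60, 1, 2),
                     is_dmc = c(TRUE, FALSE, FALSE))
  expect_equal(nrow(call_region_dm(d_mixed, ann)), 0L)
  alt <- call_region_dm(d_mixed, ann, count = "tested")
  expect_equal(nrow(alt), 1L)
  expect_equal(alt$n_cpg_tested, 3L)
  expect_equal(alt$n_dmc, 1L)
})

test_that("every emitted call is composed of threshold-passing DMCs", {
  sim <- sim_annotation(80, seed = 33)
  truth <- plant_coupled(sim$annotation, n_per_mode = 8, seed = 33)
  met <- simulate_methylome(sim$annotation, sim$cpg_sites, truth, seed = 33)
  dm <- call_dmcs(met$cpg, met$samples, "melan-a", "4C11+")
  calls <- call_region_dm(dm, sim$annotation)
  expect_gt(nrow(calls), 0)
  expect_true(all(calls$n_dmc >= 3))
  expect_true(all(calls$n_dmc <= calls$n_cpg_tested))
  members <- dplyr::semi_join(
    assign_regions(dm, sim$annotation),
    calls, by = c("gene_id", "region")
  ) |> dplyr::filter(is_dmc)
  expect_true(all(members$q_value <= 0.01))
  expect_true(all(abs(members$meth_diff) >= 25))
})
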