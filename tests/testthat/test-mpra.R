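test_that("VIP/MPRA join matches on variant id and mapped class", {
  vip <- tibble::tibble(variant_id = paste0("v", 1:10), model = "bipolar_model",
                        vip = rnorm(10))
  mpra <- tibble::tibble(variant_id = paste0("v", 3:10), cell_class = "bipolar",
                         expression_change = rnorm(8))
  expect_message(
    j <- join_vip_mpra(vip, mpra, c(bipolar_model = "bipolar")),
    "2 variant")
  expect_equal(nrow(j), 8L)
  expect_true(all(c("vip", "expression_change") %in% names(j)))

  none <- dplyr::mutate(mpra, cell_class = "rods")
  expect_error(join_vip_mpra(vip, none, c(bipolar_model = "bipolar")), "no overlap")

  # one model mapped to two MPRA classes scores against both
  both <- dplyr::bind_rows(mpra, dplyr::mutate(mpra, cell_class = "rods"))
  map2 <- c(bipolar_model = "bipolar", bipolar_model = "rods")
  j2 <- suppressMessages(join_vip_mpra(vip, both, map2))
  expect_equal(nrow(j2), 16L)

  dup <- dplyr::bind_rows(vip, vip[1, ])
  expect_error(join_vip_mpra(dup, mpra, c(bipolar_model = "bipolar")), "duplicate")
})

test_that("Pearson correlation matches hand-computed cases and its invariances", {
  expect_equal(pearson_correlation(c(1, 2, 3), c(2, 4, 6)), 1.0)
  expect_equal(pearson_correlation(c(1, 2, 3), c(3, 2, 1)), -1.0)
  expect_equal(pearson_correlation(c(0, 1, 2, 3), c(0, 1, 0, 1)),
               0.4472, tolerance = 1e-4)
  expect_error(pearson_correlation(c(1, 2), c(1, 2)), "3")
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")

  withr::with_seed(1, { x <- rnorm(30); y <- x + rnorm(30) })
  r <- pearson_correlation(x, y)
  expect_equal(pearson_correlation(2 * x + 7, 0.5 * y - 3), r, tolerance = 1e-12)
  expect_equal(pearson_correlation(-x, y), -r, tolerance = 1e-12)
})

test_that("per-class correlations exclude tiny classes and keep context", {
  withr::with_seed(2, {
    base <- tibble::tibble(variant_id = paste0("v", 1:20),
                           model = "m", vip = rnorm(20))
    joined <- dplyr::bind_rows(
      dplyr::mutate(base, cell_class = "a",
                    expression_change = vip + rnorm(20, sd = 0.1),
                    reference_expression = 5),
      dplyr::mutate(base, cell_class = "b",
                    expression_change = vip + rnorm(20, sd = 0.1),
                    reference_expression = 1),
      dplyr::mutate(base[1:2, ], cell_class = "tiny",
                    expression_change = rnorm(2), reference_expression = 0)
    )
  })
  expect_message(cc <- correlation_by_class(joined), "tiny")
  expect_equal(sort(cc$cell_class), c("a", "b"))
  expect_true(all(cc$r > 0.9))
  expect_equal(cc$mean_reference_expression[cc$cell_class == "a"], 5)

  same <- dplyr::filter(joined, cell_class != "tiny")
  same$expression_change <- rep(same$expression_change[same$cell_class == "a"], 2)
  cc2 <- correlation_by_class(same)
  expect_equal(cc2$r[1], cc2$r[2])
})

test_that("simulated reporter expression is exactly linear in motif content", {
  sim <- get_small_sim()
  motifs <- sim$motifs
  # construct with exactly one instance of classA's private motif
  m1 <- motifs$motif_id[grepl("^classA$", motifs$class)][1]
  cons <- motifs$consensus[motifs$motif_id == m1]
  withr::with_seed(3, bg <- random_dna(1, 120, gc = 0.41))
  construct <- paste0(substr(bg, 1, 50), cons, substr(bg, 59, 120))

  # deletion of the whole instance at zero noise
  del <- tibble::tibble(id = "del1", pos = 50L, ref = cons, alt = "")
  # a variant far from the motif
  far_ref <- substr(construct, 101, 101)
  far <- tibble::tibble(id = "far", pos = 100L, ref = far_ref,
                        alt = setdiff(c("A", "C", "G", "T"), far_ref)[1])
  mp <- simulate_mpra(construct, dplyr::bind_rows(del, far), motifs, sim$truth,
                      noise_sd = 0, seed = 4)
  hit_frac <- function(seq, id) {
    pwm <- pwm_logodds(motifs$pfm[[which(motifs$motif_id == id)]])
    hits <- crevip:::cpp_pwm_scan(seq, pwm, -1e9)
    h <- max(hits$score) / pwm_max_score(pwm)
    if (h < 0.8) 0 else h  # below the binding threshold counts as no site
  }
  beta <- sim$truth$beta[[m1]]
  expected <- beta * (hit_frac(apply_variant(construct, 50, cons, ""), m1) -
                        hit_frac(construct, m1))
  got <- mp$expression_change[mp$variant_id == "del1" & mp$cell_class == "classA"]
  expect_equal(got, expected, tolerance = 1e-9)
  expect_lt(got, 0)

  # non-touching variant changes nothing at zero noise (classA)
  expect_equal(mp$expression_change[mp$variant_id == "far" &
                                      mp$cell_class == "classA"], 0,
               tolerance = 1e-9)
  # classC's grammar is absent from the construct: pure zeros at zero noise
  expect_true(all(abs(mp$expression_change[mp$cell_class == "classC"]) < 1e-9))
})
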