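test_that("population maps are validated", {
  expect_s3_class(toy_pop_map(), "tbl_df")
  expect_error(population_map("a", "P5"), class = "dfbf_config_error")
  expect_error(population_map(c("a", "a", "b", "c"),
                              c("P1", "P2", "P3", "O")),
               class = "dfbf_config_error")
  expect_error(population_map(c("a", "b", "c"), c("P1", "P2", "P3")),
               regexp = "no sample for role", class = "dfbf_config_error")
})

test_that("polarization keeps fixed-difference sites and drops filtered ones", {
  pm <- toy_pop_map()
  site <- polarize_site(c(p1_a = "A", p2_a = "T", p3_a = "T", out_a = "A"), pm)
  expect_equal(site[c("p1", "p2", "p3", "pO")],
               tibble::tibble(p1 = 0, p2 = 1, p3 = 1, pO = 0),
               ignore_attr = TRUE)

  # outgroup carries both alleles -> dropped
  pm2 <- population_map(c("a", "b", "c", "o1", "o2"),
                        c("P1", "P2", "P3", "O", "O"))
  drop <- polarize_site(c(a = "A", b = "T", c = "T", o1 = "A", o2 = "T"), pm2)
  expect_true(is_site_drop(drop))
  expect_equal(drop$reason, "outgroup-polymorphic")

  # three observed alleles -> dropped
  drop <- polarize_site(c(p1_a = "A", p2_a = "T", p3_a = "C", out_a = "A"), pm)
  expect_equal(drop$reason, "multiallelic")

  # all same base -> monomorphic
  drop <- polarize_site(c(p1_a = "G", p2_a = "G", p3_a = "G", out_a = "G"), pm)
  expect_equal(drop$reason, "monomorphic")

  # missing outgroup call -> insufficient data
  drop <- polarize_site(c(p1_a = "A", p2_a = "T", p3_a = "T", out_a = "N"), pm)
  expect_equal(drop$reason, "insufficient-data")

  expect_error(polarize_site(c(p1_a = "A", p2_a = "W", p3_a = "T",
                               out_a = "A"), pm, pos = 7L),
               regexp = "position 7", class = "dfbf_input_error")
})

test_that("the outgroup allele is ancestral even when globally minor", {
  pm2 <- population_map(c("a1", "a2", "b1", "c1", "o1"),
                        c("P1", "P1", "P2", "P3", "O"))
  # outgroup monomorphic T although T is the rarer allele overall
  site <- polarize_site(c(a1 = "A", a2 = "A", b1 = "A", c1 = "A", o1 = "T"),
                        pm2)
  expect_false(is_site_drop(site))
  expect_equal(site[c("p1", "p2", "p3")],
               tibble::tibble(p1 = 1, p2 = 1, p3 = 1),
               ignore_attr = TRUE)
})

test_that("call_sites computes per-role frequencies over non-missing calls", {
  pm <- population_map(c("a1", "a2", "b1", "b2", "c1", "o1"),
                       c("P1", "P1", "P2", "P2", "P3", "O"))
  m <- rbind(a1 = c("A", "T"), a2 = c("T", "N"), b1 = c("T", "T"),
             b2 = c("T", "T"), c1 = c("T", "T"), o1 = c("A", "A"))
  s <- call_sites(m, pm)
  expect_equal(nrow(s), 2L)
  expect_equal(s$p1, c(0.5, 1))    # second site: one missing P1 call
  expect_equal(s$n1, c(2L, 1L))
  expect_equal(s$p2, c(1, 1))
  expect_equal(s$pO, c(0, 0))
})

test_that("pattern weights match closed-form hand evaluations", {
  w <- pattern_weights(make_pattern_fixture(1, 0, 1, 1))
  expect_equal(w$d13, 1); expect_equal(w$d23, 0)
  expect_equal(w$abba, 1); expect_equal(w$baba, 0); expect_equal(w$bbaa, 0)

  w <- pattern_weights(make_pattern_fixture(1, 0.2, 0.8, 1.0))
  expect_equal(w$d13, 0.8); expect_equal(w$d23, 0.2)
  expect_equal(w$abba, 0.64); expect_equal(w$baba, 0.04)
  expect_equal(w$bbaa, 0)

  w <- pattern_weights(make_pattern_fixture(1, 0.1, 0.6, 0.8))
  expect_equal(w$d13, 0.74); expect_equal(w$d23, 0.44)
  expect_equal(w$abba, 0.432); expect_equal(w$baba, 0.032)
  expect_equal(w$bbaa, 0.012)
  expect_equal(w$p2 * w$d13, w$abba + w$bbaa)   # 0.444
  expect_equal(w$p1 * w$d23, w$baba + w$bbaa)   # 0.044

  bad <- make_pattern_fixture(1, 0, 1, 1)
  bad$p2 <- 1.2
  expect_error(pattern_weights(bad), class = "dfbf_domain_error")
})

test_that("distance and pattern-count forms obey the linking identities", {
  s <- random_sites(1000, seed = 42)
  w <- pattern_weights(s)
  expect_true(all(abs(w$p2 * w$d13 - w$p1 * w$d23 -
                        (w$abba - w$baba)) <= 1e-12))
  expect_true(all(abs(w$p2 * w$d13 + w$p1 * w$d23 -
                        (w$abba + w$baba + 2 * w$bbaa)) <= 1e-12))
})

test_that("swapping P1 and P2 swaps abba<->baba and d13<->d23", {
  s <- random_sites(200, seed = 7)
  w <- pattern_weights(s)
  ws <- pattern_weights(swap_p1_p2(s))
  expect_equal(ws$abba, w$baba)
  expect_equal(ws$baba, w$abba)
  expect_equal(ws$d13, w$d23)
  expect_equal(ws$d23, w$d13)
})

test_that("no pattern weight survives a fully ancestral configuration", {
  w <- pattern_weights(make_pattern_fixture(1, 0, 0, 0))
  expect_equal(unlist(w[c("abba", "baba", "bbaa")], use.names = FALSE),
               c(0, 0, 0))
})
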