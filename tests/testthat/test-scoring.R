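test_that("subscore equals the tanh closed form and respects its domain", {
  # 2/(1+exp(-x)) - 1 == tanh(x/2); the oracle is evaluated independently
  expect_equal(subscore(0, 1), 0)
  expect_equal(subscore(3, 1), tanh(3 / 2), tolerance = 1e-12)
  expect_equal(subscore(10, 0.5), tanh(0.5 * 10 / 2), tolerance = 1e-12)
  set.seed(11)
  n <- runif(200, 0, 50)
  a <- runif(200, 0.01, 5)
  for (i in seq_along(n)) {
    expect_equal(subscore(n[i], a[i]), tanh(a[i] * n[i] / 2), tolerance = 1e-12)
  }
  expect_error(subscore(-1, 1), class = "ppiref_usage_error")
  expect_error(subscore(1, 0), class = "ppiref_usage_error")
})

test_that("subscore saturates and is exactly symmetric in alpha*n", {
  expect_gt(subscore(3, 1), 0.9)
  expect_identical(subscore(3, 1), subscore(2, 1.5))  # both alpha*n = 3
  expect_true(all(diff(subscore(0:20, 0.5)) > 0))     # strictly increasing
  expect_lt(subscore(15, 1), 1)
  expect_lte(subscore(1e4, 5), 1)  # saturates to 1 only at double precision
})

test_that("technique evidence sums reliabilities once per distinct code", {
  cfg <- score_config()
  # two-hybrid + co-immunoprecipitation: both reliability 5
  expect_equal(technique_evidence(c("MI:0018", "MI:0019"), cfg), 10)
  expect_equal(technique_evidence(character(), cfg), 0)
  # NMR (10) + RNAi (1) + two-hybrid (5)
  expect_equal(technique_evidence(c("MI:0077", "MI:1060", "MI:0018"), cfg), 16)
  # repeats of the same code do not add
  expect_equal(technique_evidence(rep("MI:0018", 4), cfg), 5)
  # unknown codes fall back to the lowest anchor class, with a warning
  expect_warning(v <- technique_evidence(c("MI:0018", "MI:9999"), cfg),
                 "MI:9999")
  expect_equal(v, 6)
})

test_that("score config validates weights, rates and reliabilities", {
  expect_error(score_config(w_s = 0.5, w_o = 0.1, w_t = 0.3),
               class = "ppiref_usage_error")
  expect_error(score_config(alpha_s = 0), class = "ppiref_usage_error")
  rel <- default_reliability(); rel$reliability[1] <- 11
  expect_error(score_config(reliability = rel), class = "ppiref_usage_error")
  cfg <- score_config(w_s = 1 / 3, w_o = 1 / 3, w_t = 1 / 3)
  expect_s3_class(cfg, "score_config")
})

test_that("confidence score is the weighted sum of the three tanh terms", {
  b0 <- make_bundles(cbind(1, 2), studies = list(character()),
                     techniques = list(character()))
  expect_equal(unname(confidence_score(b0[1, ])["score"]), 0)

  # 2 studies, 1 interolog species, techniques summing to 10
  b1 <- make_bundles(cbind(1, 2), studies = list(c("pubmed:1", "pubmed:2")),
                     techniques = list(c("MI:0018", "MI:0019")),
                     species = list("9606"))
  expected1 <- 0.6 * tanh(2 / 2) + 0.1 * tanh(1.5 * 1 / 2) + 0.3 * tanh(0.5 * 10 / 2)
  expect_equal(unname(confidence_score(b1[1, ])["score"]), expected1,
               tolerance = 1e-12)

  # 3 studies, 2 species, technique sum 10: all three saturation points
  b2 <- make_bundles(cbind(1, 2),
                     studies = list(paste0("pubmed:", 1:3)),
                     techniques = list(c("MI:0018", "MI:0019")),
                     species = list(c("9606", "559292")))
  expected2 <- 0.6 * tanh(1.5) + 0.1 * tanh(1.5) + 0.3 * tanh(2.5)
  sc <- confidence_score(b2[1, ])
  expect_equal(unname(sc["score"]), expected2, tolerance = 1e-12)
  # decomposition invariant
  expect_equal(unname(sc["score"]),
               unname(0.6 * sc["s_s"] + 0.1 * sc["s_o"] + 0.3 * sc["s_t"]),
               tolerance = 1e-12)
})

test_that("every score lies in [0, 1) and matches the term-by-term oracle", {
  set.seed(5)
  cfg <- score_config()
  rel <- stats::setNames(cfg$reliability$reliability, cfg$reliability$mi_code)
  for (i in 1:50) {
    ns <- sample(0:6, 1); no <- sample(0:4, 1)
    techs <- sample(cfg$reliability$mi_code, sample(0:4, 1))
    b <- make_bundles(cbind(1, 2),
                      studies = list(if (ns) paste0("pubmed:", 1:ns) else character()),
                      techniques = list(techs),
                      species = list(if (no) as.character(9600 + 1:no) else character()))
    s <- unname(confidence_score(b[1, ], cfg)["score"])
    oracle <- 0.6 * tanh(ns / 2) + 0.1 * tanh(1.5 * no / 2) +
      0.3 * tanh(0.5 * sum(rel[techs]) / 2)
    expect_equal(s, oracle, tolerance = 1e-12)
    expect_gte(s, 0); expect_lt(s, 1)
  }
})

test_that("scores never decrease when evidence is added", {
  set.seed(9)
  for (i in 1:20) {
    ns <- sample(1:4, 1)
    techs <- sample(default_reliability()$mi_code, sample(1:3, 1))
    spc <- as.character(9600 + seq_len(sample(0:2, 1)))
    base <- make_bundles(cbind(1, 2), studies = list(paste0("p", 1:ns)),
                         techniques = list(techs), species = list(spc))
    s0 <- confidence_score(base[1, ])["score"]
    more_study <- base; more_study$studies[[1]] <- c(base$studies[[1]], "p_extra")
    expect_gte(confidence_score(more_study[1, ])["score"], s0)
    more_sp <- base; more_sp$interolog_species[[1]] <- c(spc, "7227")
    expect_gte(confidence_score(more_sp[1, ])["score"], s0)
    new_t <- setdiff(default_reliability()$mi_code, techs)
    if (length(new_t)) {
      more_t <- base; more_t$techniques[[1]] <- c(techs, new_t[1])
      expect_gte(confidence_score(more_t[1, ])["score"], s0)
    }
  }
})

test_that("rescore maps the per-bundle score and honours custom parameters", {
  set.seed(3)
  b <- make_bundles(cbind(1:20, 21:40),
                    studies = lapply(1:20, function(i) paste0("p", seq_len(sample(1:4, 1)))),
                    techniques = lapply(1:20, function(i)
                      sample(default_reliability()$mi_code, sample(1:3, 1))))
  scored <- rescore(b)
  expect_equal(scored$score,
               vapply(seq_len(nrow(b)), function(i)
                 unname(confidence_score(b[i, ])["score"]), numeric(1)))
  # permutation invariance
  perm <- sample(nrow(b))
  scored_perm <- rescore(b[perm, ])
  expect_equal(scored_perm$score, scored$score[perm])
  # studies-only weights reduce the score to the study sub-score
  only_s <- rescore(b, score_config(w_s = 1, w_o = 0, w_t = 0))
  expect_equal(only_s$score, subscore(lengths(b$studies), 1))
  # doubling technique reliabilities never decreases any score
  rel2 <- default_reliability(); rel2$reliability <- pmin(10, rel2$reliability * 2)
  expect_true(all(rescore(b, score_config(reliability = rel2))$score >=
                    scored$score - 1e-12))
})

test_that("confidence levels are type-7 quartiles and presets are the published cutoffs", {
  expect_equal(confidence_levels(c(0.2, 0.4, 0.6, 0.8)),
               c(medium = 0.5, high = 0.65))
  expect_equal(confidence_levels(rep(0.37, 9)), c(medium = 0.37, high = 0.37))
  expect_error(confidence_levels(numeric()), class = "ppiref_usage_error")
  expect_equal(confidence_presets(), c(medium = 0.53, high = 0.6))
  expect_equal(default_tpm_threshold(), 1)
})

test_that("scored tables round-trip through TSV", {
  b <- make_bundles(cbind(c(1, 3), c(2, 4)),
                    studies = list(c("p1", "p2"), "p3"),
                    techniques = list("MI:0018", c("MI:0019", "MI:0077")),
                    species = list("9606", character()))
  scored <- rescore(b)
  path <- tempfile()
  write_scored(scored, path)
  back <- read_scored(path)
  expect_equal(back$score, scored$score)
  expect_equal(back$studies, unname(scored$studies))
  expect_equal(back$interolog_species, unname(scored$interolog_species))
})

test_that("key=value config files override defaults and reject unknown keys", {
  rel <- tempfile(); cfg <- tempfile()
  utils::write.table(default_reliability(), rel, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(c("w_s=1", "w_o=0", "w_t=0", "alpha_s=2",
               paste0("reliability=", rel)), cfg)
  c2 <- read_score_config(cfg)
  expect_equal(c2$w_s, 1); expect_equal(c2$alpha_s, 2)
  writeLines("nonsense=1", cfg)
  expect_error(read_score_config(cfg), class = "ppiref_format_error")
})
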