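# mpc_model with a single active feature (weight 1, intercept 0), so the
# fitted value of a variant equals its sub_overall_oe feature and rank
# behavior can be controlled exactly.
manual_model <- function(benign_fitted, floor = 0.83) {
  feats <- mpc_features()
  coefs <- stats::setNames(rep(0, length(feats) + 1),
                           c("(Intercept)", feats))
  coefs["sub_overall_oe"] <- 1
  structure(
    list(coefficients = coefs, benign_fitted = sort(benign_fitted),
         M = length(benign_fitted), floor = floor, features = feats,
         n_pathogenic = 0L),
    class = "mpc_model"
  )
}

variant_with_fitted <- function(x) {
  df <- tibble::as_tibble(stats::setNames(
    as.list(rep(0, length(mpc_features()))), mpc_features()
  ))
  df <- df[rep(1, length(x)), ]
  df$sub_overall_oe <- x
  df
}

test_that("second differences behave on constant and quadratic profiles", {
  expect_equal(rmcr:::second_difference(rep(0.5, 10)), rep(0, 10))
  # quadratic a*i^2: central second difference is 2a everywhere
  a <- 0.03
  v <- a * (1:10)^2
  expect_equal(rmcr:::second_difference(v), rep(2 * a, 10))
  expect_true(all(is.na(rmcr:::second_difference(c(1, 2)))))
})

test_that("substitution metrics match hand computation on a toy universe", {
  # class X: 2/4 observed in bin 1 sites (exp 4), 4/4 in bin 10 (exp 4)
  # class Y: 0 observed anywhere
  sites <- tibble::tibble(
    aa_sub = rep(c("X", "Y"), each = 8),
    observed = c(rep(c(TRUE, FALSE), 2), rep(TRUE, 4), rep(FALSE, 8)),
    mu_adj = 1,
    local_oe = rep(rep(c(0.05, 0.95), each = 4), 2)
  )
  m <- substitution_metrics(sites)
  mx <- dplyr::filter(m, aa_sub == "X")
  expect_equal(unique(mx$overall_oe), 6 / 8)
  expect_equal(mx$oe_by_bin[mx$bin == 1], 0.5)
  expect_equal(mx$oe_by_bin[mx$bin == 10], 1)
  my <- dplyr::filter(m, aa_sub == "Y")
  expect_equal(unique(my$overall_oe), 0)
  expect_equal(nrow(m), 20)  # 2 classes x 10 bins
})

test_that("oe bins are left-closed right-open with a closed final bin", {
  expect_equal(oe_bin(c(0, 0.1, 0.95, 1)), c(1L, 2L, 10L, 10L))
})

test_that("training assembly applies gene, review, and overlap rules", {
  clinvar <- tibble::tibble(
    variant_id = sprintf("c%d", 1:6),
    gene = c("G1", "G1", "G2", "G3", "G1", "G1"),
    classification = c("Pathogenic", "Likely pathogenic", "Pathogenic",
                       "Pathogenic", "Benign", "Pathogenic"),
    conflicting = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stars = c(1L, 2L, 1L, 0L, 1L, 1L)
  )
  phaplo <- tibble::tibble(gene = c("G1", "G2", "G3"),
                           phaplo = c(0.9, 0.5, 0.95))
  population <- tibble::tibble(
    variant_id = c("b1", "b2", "b3", "b4", "c1"),
    allele_freq = c(0.01, 0.005, 0.0005, 0.02, 0.01),
    qc_pass = c(TRUE, TRUE, TRUE, FALSE, TRUE)
  )
  # c1/c2 qualify via pHaplo G1; c3 fails (G2 below cutoff) unless in dd
  # list; c4 fails stars; c5 is benign classification; c6 conflicting.
  # c1 also matches the benign set -> dropped from both.
  sets <- assemble_training_sets(clinvar, phaplo, dd_genes = character(0),
                                 population = population)
  expect_setequal(sets$pathogenic$variant_id, "c2")
  expect_setequal(sets$benign$variant_id, c("b1", "b2"))
  # DD gene list rescues G2
  sets2 <- assemble_training_sets(clinvar, phaplo, dd_genes = "G2",
                                  population = population)
  expect_true("c3" %in% sets2$pathogenic$variant_id)
  # pHaplo boundary is inclusive
  sets3 <- assemble_training_sets(
    clinvar, tibble::tibble(gene = "G1", phaplo = 0.86),
    dd_genes = character(0), population = population
  )
  expect_true("c2" %in% sets3$pathogenic$variant_id)
})

test_that("stratified split is exhaustive, sized, and order-invariant", {
  transcripts <- tibble::tibble(
    transcript_id = sprintf("T%03d", 1:10),
    s_het = rep(0.1, 10),
    n_possible = rep(500L, 10)
  )
  sp <- stratified_split(transcripts, train_frac = 0.8, seed = 4)
  expect_equal(length(sp$train), 8)
  expect_equal(length(sp$test), 2)
  expect_setequal(c(sp$train, sp$test), transcripts$transcript_id)
  # same seed, permuted rows -> identical split
  sp2 <- stratified_split(transcripts[sample(10), ], train_frac = 0.8,
                          seed = 4)
  expect_identical(sp, sp2)
  # stratum marginals stay near the target fraction
  big <- tibble::tibble(
    transcript_id = sprintf("T%04d", 1:400),
    s_het = rep(c(0.01, 0.5), 200),
    n_possible = rep(c(100L, 2000L), each = 200)
  )
  spb <- stratified_split(big, train_frac = 0.8, seed = 4)
  by_stratum <- big %>%
    dplyr::mutate(train = transcript_id %in% spb$train) %>%
    dplyr::group_by(s_het, n_possible) %>%
    dplyr::summarise(frac = mean(train), n = dplyr::n(), .groups = "drop")
  expect_true(all(abs(by_stratum$frac - 0.8) * by_stratum$n <= 1))
})

test_that("rank transform reproduces the printed deleteriousness values", {
  M <- 64023L
  expect_equal(mpc_transform(M, M), 0)
  expect_equal(mpc_transform(M / 10, M), 1, tolerance = 1e-12)
  expect_equal(mpc_transform(0, M), log10(M / 0.83), tolerance = 1e-12)
  expect_equal(mpc_transform(0, M), 4.887257928149, tolerance = 1e-9)
  # transform is monotone non-increasing in fi and bounded
  d <- mpc_transform(0:M, M)
  expect_true(all(diff(d) <= 0))
  expect_true(all(d >= 0 & d <= log10(M / 0.83)))

  # the same identities through a full model and fitted-value ranks
  model <- manual_model(seq_len(M) / M)
  # below every benign variant (least pathogenic-looking): fi = M, score 0
  expect_equal(mpc_score(model, variant_with_fitted(-1))$mpc, 0)
  # above every benign variant: fi = 0, the floored maximum score
  expect_equal(mpc_score(model, variant_with_fitted(2))$mpc,
               log10(M / 0.83), tolerance = 1e-9)
  # fitted between the (M - 6402)th and next benign value: fi = 6402 ~ M/10
  x <- (M - 6402 + 0.5) / M
  expect_equal(mpc_score(model, variant_with_fitted(x))$mpc,
               -log10(6402 / M), tolerance = 1e-12)
})

test_that("scores are monotone in the fitted value and bounded", {
  model <- manual_model(runif(500))
  x <- sort(runif(200, -0.5, 1.5))
  d <- mpc_score(model, variant_with_fitted(x))$mpc
  expect_true(all(diff(d) >= -1e-12))  # more pathogenic-looking -> larger d
  expect_true(all(d >= 0 & d <= log10(model$M / model$floor) + 1e-12))
})

test_that("ties with benign fitted values do not count toward the rank", {
  model <- manual_model(c(0.1, 0.2, 0.2, 0.3))
  # fitted exactly 0.2: only the one strictly greater benign value counts
  expect_equal(mpc_score(model, variant_with_fitted(0.2))$mpc,
               -log10(1 / 4))
})

test_that("scores are invariant under monotone transforms of fitted values", {
  benign <- withr::with_seed(8, runif(300, -2, 2))
  x <- withr::with_seed(9, runif(50, -2.5, 2.5))
  f <- function(v) exp(3 * v) - 1  # strictly monotone
  d1 <- mpc_score(manual_model(benign), variant_with_fitted(x))$mpc
  d2 <- mpc_score(manual_model(f(benign)), variant_with_fitted(f(x)))$mpc
  expect_equal(d1, d2)
})

test_that("missing features yield NA scores, never zero", {
  model <- manual_model(runif(100))
  v <- variant_with_fitted(c(0.5, NA))
  d <- mpc_score(model, v)$mpc
  expect_false(is.na(d[1]))
  expect_true(is.na(d[2]))
})

test_that("fit recovers a planted single-feature effect and stores M", {
  train <- simulate_labeled_variants(400, 800,
                                     effects = c(polyphen2 = 2), seed = 10)
  model <- fit_mpc(train)
  expect_equal(model$M, 800)
  expect_equal(model$n_pathogenic, 400)
  co <- tidy(model)
  pp2 <- co$estimate[co$term == "polyphen2"]
  expect_gt(pp2, 1)  # dominant, correctly signed
  others <- co$estimate[!co$term %in% c("(Intercept)", "polyphen2")]
  expect_true(all(abs(others) < abs(pp2) / 3))
  # scores separate the classes
  scored <- mpc_score(model, train)
  expect_gt(mean(scored$mpc[train$label == 1]),
            mean(scored$mpc[train$label == 0]))
  expect_equal(glance(model)$n_benign, 800)
})

test_that("shuffled labels give near-zero coefficients", {
  train <- simulate_labeled_variants(500, 500,
                                     effects = c(polyphen2 = 2), seed = 11)
  train$label <- withr::with_seed(12, sample(train$label))
  model <- fit_mpc(train)
  co <- tidy(model)
  expect_true(all(abs(co$estimate[co$term != "(Intercept)"]) < 0.25))
})

test_that("model JSON round-trips with exact ranks", {
  train <- simulate_labeled_variants(100, 200, seed = 13)
  model <- fit_mpc(train)
  path <- withr::local_tempfile(fileext = ".json")
  write_mpc_model(model, path)
  model2 <- read_mpc_model(path)
  expect_equal(model2$coefficients, model$coefficients)
  expect_equal(model2$benign_fitted, model$benign_fitted)
  expect_equal(model2$M, model$M)
  v <- train[1:20, ]
  expect_equal(mpc_score(model2, v)$mpc, mpc_score(model, v)$mpc)
})
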