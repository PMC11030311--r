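#' OE bins over local missense constraint
#'
#' Ten left-closed, right-open bins of local OE from 0 to 1: [0, 0.1), ...,
#' [0.9, 1.0+]; the final bin absorbs OE of exactly 1 (and any value above,
#' should capping be disabled).
#'
#' @param oe Local OE values in `[0, 1]`.
#' @return Integer bin indices 1..10.
#' @export
oe_bin <- function(oe) {
  pmin(10L, as.integer(floor(oe * 10)) + 1L)
}

#' Constraint metrics per amino-acid substitution class
#'
#' Two regional-constraint features of a substitution class (e.g. "Met>Tyr"):
#' its overall OE (rare observed variants causing the substitution divided by
#' the expectation, capped at 1), and the curvature of its OE profile across
#' bins of local constraint — the per-bin OE (observed/expected of the class
#' within regions whose local OE falls in the bin) differentiated twice by
#' central second differences over bin index, one-sided at the ends.
#' Substitution classes in strongly constrained regions that remain depleted
#' show distinctive curvature.
#'
#' @param sites Site table with columns `aa_sub`, `observed`, `mu_adj`,
#'   `local_oe` (OE of the region — MCR if the transcript has several, else the
#'   transcript — containing the site).
#' @return A tibble with one row per `(aa_sub, bin)` plus per-class overall
#'   columns: `aa_sub`, `overall_oe`, `bin` (1..10), `oe_by_bin`,
#'   `second_derivative` (NA where neighboring bins are empty).
#' @export
substitution_metrics <- function(sites) {
  check_columns(sites, c("aa_sub", "observed", "mu_adj", "local_oe"), "sites")
  overall <- sites %>%
    dplyr::group_by(.data$aa_sub) %>%
    dplyr::summarise(
      overall_oe = oe_ratio(sum(.data$observed), sum(.data$mu_adj)),
      .groups = "drop"
    )
  by_bin <- sites %>%
    dplyr::mutate(bin = oe_bin(.data$local_oe)) %>%
    dplyr::group_by(.data$aa_sub, .data$bin) %>%
    dplyr::summarise(
      oe_by_bin = oe_ratio(sum(.data$observed), sum(.data$mu_adj)),
      .groups = "drop"
    ) %>%
    tidyr::complete(.data$aa_sub, bin = 1:10) %>%
    dplyr::group_by(.data$aa_sub) %>%
    dplyr::arrange(.data$bin, .by_group = TRUE) %>%
    dplyr::mutate(second_derivative = second_difference(.data$oe_by_bin)) %>%
    dplyr::ungroup()
  dplyr::left_join(overall, by_bin, by = "aa_sub")
}

# Central second differences over a unit-spaced grid; one-sided (copied from
# the nearest interior estimate) at the ends. NA where a neighbor is missing.
second_difference <- function(v) {
  n <- length(v)
  if (n < 3) return(rep(NA_real_, n))
  d2 <- rep(NA_real_, n)
  d2[2:(n - 1)] <- v[3:n] - 2 * v[2:(n - 1)] + v[1:(n - 2)]
  d2[1] <- d2[2]
  d2[n] <- d2[n - 1]
  d2
}

#' Assemble pathogenic and benign training sets
#'
#' Pathogenic candidates are clinically classified pathogenic/likely
#' pathogenic variants with non-conflicting assertions and at least one review
#' star, restricted to genes that are likely haploinsufficient (pHaplo >= 0.86)
#' or carry a dominant non-LoF developmental-disorder association. Benign
#' candidates are common (AF above the cutoff) population variants passing QC.
#' Variants qualifying for both sets are removed from both.
#'
#' @param clinvar Labeled variant table with columns `variant_id`, `gene`,
#'   `classification` (values containing "pathogenic"/"benign" etc.),
#'   `conflicting` (logical), `stars` (integer review status).
#' @param phaplo Gene table with columns `gene`, `phaplo`.
#' @param dd_genes Character vector of dominant non-LoF DD-associated genes.
#' @param population Population variant table with columns `variant_id`,
#'   `allele_freq`, `qc_pass`.
#' @param phaplo_cutoff pHaplo threshold (default 0.86).
#' @param af_cutoff Common-variant frequency cutoff (default 0.001).
#' @return A list with tibbles `pathogenic` and `benign`.
#' @export
assemble_training_sets <- function(clinvar, phaplo, dd_genes, population,
                                   phaplo_cutoff = 0.86, af_cutoff = 0.001) {
  check_columns(clinvar, c("variant_id", "gene", "classification",
                           "conflicting", "stars"), "clinvar")
  check_columns(phaplo, c("gene", "phaplo"), "phaplo")
  check_columns(population, c("variant_id", "allele_freq", "qc_pass"),
                "population")
  hi_genes <- union(phaplo$gene[phaplo$phaplo >= phaplo_cutoff], dd_genes)
  path <- clinvar %>%
    dplyr::filter(
      grepl("pathogenic", .data$classification, ignore.case = TRUE),
      !grepl("benign", .data$classification, ignore.case = TRUE),
      !.data$conflicting,
      .data$stars >= 1,
      .data$gene %in% hi_genes
    )
  benign <- population %>%
    dplyr::filter(.data$allele_freq > af_cutoff, .data$qc_pass)
  both <- intersect(path$variant_id, benign$variant_id)
  path <- dplyr::filter(path, !.data$variant_id %in% both)
  benign <- dplyr::filter(benign, !.data$variant_id %in% both)
  if (nrow(path) == 0 || nrow(benign) == 0) {
    stop("training assembly produced an empty pathogenic or benign set",
         call. = FALSE)
  }
  list(pathogenic = tibble::as_tibble(path),
       benign = tibble::as_tibble(benign))
}

#' Stratified train/test split of transcripts
#'
#' Splits transcripts into train and test sets at a target fraction within
#' joint quantile-bin strata of a selection coefficient (s_het) and the number
#' of possible missense sites, so the two sets are matched on selection
#' strength and on power to detect constraint. Transcripts missing a stratum
#' value form their own stratum. The split is canonicalized on sorted
#' transcript ids, so it is invariant to input row order given the same seed.
#'
#' @param transcripts Data frame with columns `transcript_id`, `s_het`,
#'   `n_possible`.
#' @param train_frac Target training fraction (default 0.8).
#' @param n_bins Number of quantile bins per stratifying variable (default 4).
#' @param seed Integer seed.
#' @return A list with character vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
stratified_split <- function(transcripts, train_frac = 0.8, n_bins = 4,
                             seed = 1) {
  check_columns(transcripts, c("transcript_id", "s_het", "n_possible"),
                "transcripts")
  df <- transcripts %>%
    dplyr::arrange(.data$transcript_id) %>%
    dplyr::mutate(
      s_bin = quantile_bin(.data$s_het, n_bins),
      n_bin = quantile_bin(.data$n_possible, n_bins),
      stratum = paste(.data$s_bin, .data$n_bin, sep = ":")
    )
  train_ids <- withr::with_seed(seed, {
    df %>%
      dplyr::group_by(.data$stratum) %>%
      dplyr::group_map(function(g, key) {
        n_train <- round(train_frac * nrow(g))
        sample(g$transcript_id, n_train)
      }) %>%
      unlist()
  })
  list(
    train = sort(train_ids),
    test = sort(setdiff(df$transcript_id, train_ids))
  )
}

quantile_bin <- function(x, n_bins) {
  out <- rep("missing", length(x))
  ok <- !is.na(x)
  if (any(ok)) {
    brks <- unique(stats::quantile(x[ok],
                                   probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(brks) < 2) {
      out[ok] <- "1"  # constant stratifying variable: one stratum
    } else {
      out[ok] <- as.character(cut(x[ok], brks, include.lowest = TRUE,
                                  labels = FALSE))
    }
  }
  out
}

#' Features used by the MPC logistic model
#' @export
mpc_features <- function() {
  c("sub_overall_oe", "sub_oe_second_derivative", "blosum", "grantham",
    "local_oe", "polyphen2")
}

#' Fit the MPC logistic model
#'
#' Fits a logistic regression separating pathogenic (label 1) from benign
#' (label 0) variants on six features: the variant's substitution-class
#' overall OE and OE second derivative, BLOSUM and Grantham substitution
#' severity, the local (regional or transcript) missense OE, and PolyPhen-2.
#' Only variants carrying all six features are used. The fitted values of the
#' benign training variants are stored (sorted) for the rank-based score
#' transform; their count is M.
#'
#' If the fit detects quasi-complete separation, a small ridge penalty is used
#' instead (via glmnet) so coefficients stay finite; scores depend only on the
#' rank of fitted values, so this barely perturbs them.
#'
#' @param train Data frame with a binary `label` column (1 = pathogenic) and
#'   the six feature columns of [mpc_features()].
#' @param floor Rank floor in the score transform (default 0.83).
#' @return An object of class `mpc_model`: `coefficients` (named, incl.
#'   intercept), `benign_fitted` (sorted ascending), `M`, `floor`,
#'   `features`, `n_pathogenic`.
#' @export
fit_mpc <- function(train, floor = 0.83) {
  feats <- mpc_features()
  check_columns(train, c("label", feats), "train")
  train <- train[stats::complete.cases(train[, c("label", feats)]), ]
  if (!all(train$label %in% 0:1) || length(unique(train$label)) < 2) {
    stop("`label` must contain both classes coded 0/1", call. = FALSE)
  }
  fml <- stats::as.formula(paste("label ~", paste(feats, collapse = " + ")))
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = train, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separated && requireNamespace("glmnet", quietly = TRUE)) {
    warning("separation detected in MPC fit; using a small ridge penalty",
            call. = FALSE)
    x <- as.matrix(train[, feats])
    gfit <- glmnet::glmnet(x, train$label, family = "binomial",
                           alpha = 0, lambda = 1e-4)
    beta <- c(as.numeric(gfit$a0), as.numeric(gfit$beta))
    names(beta) <- c("(Intercept)", feats)
    coefs <- beta
    lp <- drop(cbind(1, x) %*% beta)
  } else {
    coefs <- stats::coef(fit)
    lp <- stats::predict(fit, type = "link")
  }
  benign_lp <- sort(unname(lp[train$label == 0]))
  structure(
    list(
      coefficients = coefs,
      benign_fitted = benign_lp,
      M = length(benign_lp),
      floor = floor,
      features = feats,
      n_pathogenic = sum(train$label == 1)
    ),
    class = "mpc_model"
  )
}

#' @export
print.mpc_model <- function(x, ...) {
  cat(sprintf(
    "MPC model: %d features, %d pathogenic vs M = %d benign training variants\n",
    length(x$features), x$n_pathogenic, x$M
  ))
  cat(sprintf("Score range [0, %.4f]\n", -log10(x$floor / x$M)))
  invisible(x)
}

#' @param x An `mpc_model`.
#' @param ... Unused.
#' @rdname fit_mpc
#' @method tidy mpc_model
#' @export
tidy.mpc_model <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @rdname fit_mpc
#' @method glance mpc_model
#' @export
glance.mpc_model <- function(x, ...) {
  tibble::tibble(
    n_pathogenic = x$n_pathogenic,
    n_benign = x$M,
    floor = x$floor,
    max_score = -log10(x$floor / x$M)
  )
}

# Linear predictor on a feature data frame; NA where any feature is missing.
mpc_linear_predictor <- function(model, variants) {
  x <- as.matrix(variants[, model$features, drop = FALSE])
  drop(cbind(1, x) %*% model$coefficients[c("(Intercept)", model$features)])
}

#' The MPC rank transform
#'
#' `d_i = -log10(max(floor, f_i) / M)`: the negative log10 of a variant's rank
#' among the M common (benign-proxy) training variants, floored (default 0.83)
#' so the logarithm stays finite when a variant outranks every common variant.
#' Monotone non-increasing in `fi`, with range `[0, log10(M / floor)]`.
#'
#' @param fi Number of common variants the variant ranks as more deleterious
#'   than (equivalently: common variants whose benign-direction fitted value
#'   is strictly less than the variant's).
#' @param M Common (benign) training-set size.
#' @param floor Rank floor (default 0.83).
#' @return Deleteriousness scores; larger = more deleterious.
#' @export
mpc_transform <- function(fi, M, floor = 0.83) {
  stopifnot(all(fi >= 0 & fi <= M, na.rm = TRUE), M > 0)
  -log10(pmax(floor, fi) / M)
}

#' Score variants with a fitted MPC model
#'
#' The deleteriousness score of variant i is the rank-based transform
#' [mpc_transform()] of its logistic fitted value against the benign training
#' set. The rank `f_i` counts benign training variants that look *less benign*
#' than variant i — i.e. whose pathogenic-direction fitted value is strictly
#' greater than variant i's (ties do not count). A variant more
#' pathogenic-looking than every benign variant has `f_i = 0` and attains the
#' maximum score `log10(M / floor)`. Larger scores mean stronger predicted
#' deleteriousness. Variants missing any feature get `NA` (unscored), never 0.
#'
#' @param model An `mpc_model`.
#' @param variants Data frame carrying the model's feature columns (and, if
#'   present, `variant_id`/`transcript_id`, which are carried through).
#' @return The input tibble with an `mpc` column appended.
#' @export
mpc_score <- function(model, variants) {
  check_columns(variants, model$features, "variants")
  lp <- mpc_linear_predictor(model, variants)
  # benign variants with pathogenic-direction fitted value strictly above the
  # variant's = benign variants strictly below it on the benign-direction scale
  fi <- model$M - findInterval(lp, model$benign_fitted)
  d <- mpc_transform(fi, model$M, model$floor)
  d[is.na(lp)] <- NA_real_
  dplyr::mutate(tibble::as_tibble(variants), mpc = d)
}

#' Persist / restore an MPC model as JSON
#'
#' Stores coefficients, feature names, the full sorted benign fitted values
#' (exact-count storage, bit-reproducible ranks), M and the floor.
#'
#' @param model An `mpc_model`.
#' @param path File path.
#' @return `write_mpc_model` returns `path` invisibly; `read_mpc_model`
#'   returns an `mpc_model`.
#' @export
write_mpc_model <- function(model, path) {
  jsonlite::write_json(
    list(
      coefficients = as.list(model$coefficients),
      features = model$features,
      benign_fitted = model$benign_fitted,
      M = model$M,
      floor = model$floor,
      n_pathogenic = model$n_pathogenic
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_mpc_model
#' @export
read_mpc_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      coefficients = unlist(j$coefficients),
      benign_fitted = as.numeric(j$benign_fitted),
      M = as.integer(j$M),
      floor = as.numeric(j$floor),
      features = as.character(j$features),
      n_pathogenic = as.integer(j$n_pathogenic)
    ),
    class = "mpc_model"
  )
}
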