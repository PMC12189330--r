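# rolling polynomial hash over a serialized object, for provenance blocks
.fnv1a <- function(obj) {
  bytes <- as.integer(serialize(obj, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full decomposition and discrimination pipeline
#'
#' Chains every stage end to end: validation and ordering, reference-subset
#' extraction, inbreeding and Mendelian sampling variances, the MSV / NCA /
#' founder decompositions with conservation checks, feature assembly,
#' collinearity screening, stepwise selection, the canonical discriminant
#' fit with its significance tests, leave-one-out classification, Mahalanobis
#' centroid distances and the dendrogram. When the population carries no
#' inbreeding, or too few labeled groups remain, the discriminant stages are
#' skipped with an explanatory notice rather than an error.
#'
#' @param pedigree a `pedigree` object or path to a pedigree CSV.
#' @param config optional named list overriding defaults: `level`
#'   ("province" or "municipality"), `vif_threshold` (5), `priors`
#'   ("proportional"/"uniform"), `linkage` ("average"/"single"/"complete"),
#'   `loadings_threshold` (0.4), `min_group_size` (2), `stepwise` (TRUE),
#'   `reference` (list of [subset_population()] rules; default keeps animals
#'   with both parents known).
#' @return a `pipeline_report` list with elements `population`, `summary`,
#'   `descriptive`, `features`, `screen`, `selection`, `cda`, `tests`,
#'   `classification`, `distances`, `dendrogram`, `conservation`, `notices`
#'   and `provenance`.
#' @export
run_full_pipeline <- function(pedigree, config = list()) {
  cfg <- utils::modifyList(list(level = "province", vif_threshold = 5,
                                priors = "proportional", linkage = "average",
                                loadings_threshold = 0.4, min_group_size = 2,
                                stepwise = TRUE,
                                reference = list(both_parents_known = TRUE)),
                           config)
  ped <- if (inherits(pedigree, "pedigree")) validate_and_order(pedigree)
         else read_pedigree(pedigree)
  notices <- character(0)

  ref <- do.call(subset_population,
                 c(list(ped = ped, name = "reference"), cfg$reference))
  if (ref$n == 0) stop("reference population is empty")

  F <- compute_inbreeding(ped)
  b <- mendelian_sampling_variances(ped, F)
  Fbar <- mean(F[ref$member_ids])
  fbar <- group_mean_coancestry(ped, ref$member_ids)
  alpha <- nonrandom_mating_alpha(Fbar, fbar$coancestry)

  m_F <- msv_decomposition_group(ped, ref$member_ids, "mean_F", b = b)
  m_f <- msv_decomposition_group(ped, ref$member_ids, "mean_coancestry", b = b)
  u_F <- nca_contributions(ped, m_F)
  u_f <- nca_contributions(ped, m_f)
  v_F <- founder_contributions(ped, u_F)
  v_f <- founder_contributions(ped, u_f)
  conservation <- data.frame(
    target = c("mean_F", "mean_coancestry"),
    statistic = c(Fbar, fbar$coancestry),
    msv_total = c(m_F$total, m_f$total),
    nca_total = c(u_F$total, u_f$total),
    founder_total = c(v_F$total, v_f$total))
  conservation$max_residual <- pmax(
    abs(conservation$msv_total - conservation$statistic),
    abs(conservation$nca_total - conservation$statistic),
    abs(conservation$founder_total - conservation$statistic))
  if (any(conservation$max_residual > 1e-8))
    warning("conservation residual above 1e-8; inspect the pedigree")

  features <- assemble_ancestor_features(ped, ref$member_ids)
  num <- c("loop_contribution", "founder_to_meanF", "founder_to_meanCoancestry",
           "coancestry_C", "alpha")
  descriptive <- do.call(rbind, lapply(num, function(v) data.frame(
    variable = v, mean = mean(features[[v]]), min = min(features[[v]]),
    max = max(features[[v]]), sd = stats::sd(features[[v]]))))

  group <- factor(features[[cfg$level]])
  keep_g <- names(table(group))[table(group) >= cfg$min_group_size]
  usable <- !is.na(group) & group %in% keep_g

  screen <- selection <- cda <- tests <- classification <- NULL
  distances <- dendro <- NULL
  if (Fbar == 0 && fbar$coancestry == 0) {
    notices <- c(notices, "no inbreeding or coancestry in the reference population; discriminant stages skipped")
  } else if (sum(usable) < 8 || length(keep_g) < 2) {
    notices <- c(notices, "fewer than 2 usable origin groups; discriminant stages skipped")
  } else {
    feats <- features[usable, , drop = FALSE]
    group <- droplevels(group[usable])
    screen <- tryCatch(collinearity_screen(feats[num], threshold = cfg$vif_threshold),
                       error = function(e) e)
    if (inherits(screen, "error")) {
      notices <- c(notices, paste("collinearity screen:", conditionMessage(screen)))
      surv <- num[c(1, 2)]
    } else surv <- names(screen$vif)
    if (isTRUE(cfg$stepwise) && length(surv) > 1) {
      selection <- stepwise_variable_selection(feats[surv], group)
      if (length(selection$selected)) surv <- selection$selected
    }
    cda <- fit_canonical_discriminant(feats[surv], group)
    tests <- discriminant_significance_tests(cda)
    classification <- loocv_classification(feats[surv], group, priors = cfg$priors)
    distances <- mahalanobis_centroid_distances(cda)
    dendro <- if (nrow(distances) >= 2)
      distance_dendrogram(distances, linkage = cfg$linkage) else NULL
  }

  structure(list(
    population = list(n_total = nrow(ped), n_founders = sum(attr(ped, "founder")),
                      reference = ref),
    summary = list(mean_F = Fbar, mean_coancestry = fbar$coancestry,
                   mean_relationship = fbar$relationship, alpha = alpha),
    descriptive = descriptive,
    features = features,
    screen = if (inherits(screen, "error")) NULL else screen,
    selection = selection,
    cda = cda, tests = tests, classification = classification,
    distances = distances, dendrogram = dendro,
    decomposition = list(msv_meanF = m_F, msv_meanf = m_f,
                         nca_meanF = u_F, nca_meanf = u_f,
                         founders_meanF = v_F, founders_meanf = v_f),
    conservation = conservation,
    notices = notices,
    provenance = list(config = cfg, config_hash = .fnv1a(cfg),
                      pedigree_hash = .fnv1a(as.data.frame(ped)),
                      package_version = as.character(utils::packageVersion("pedloops")))
  ), class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("pipeline report: %d animals, reference n = %d\n",
              x$population$n_total, x$population$reference$n))
  cat(sprintf("  mean F = %.6g, mean coancestry = %.6g, alpha = %.6g\n",
              x$summary$mean_F, x$summary$mean_coancestry, x$summary$alpha))
  cat(sprintf("  conservation max residual: %.2e\n", max(x$conservation$max_residual)))
  if (!is.null(x$classification))
    cat(sprintf("  LOOCV hit ratio %.3f, Press's Q %.2f\n",
                x$classification$hit_ratio, x$classification$press_q))
  for (nt in x$notices) cat("  note:", nt, "\n")
  invisible(x)
}

.fmt6 <- function(x) {
  if (is.numeric(x)) formatC(signif(x, 6), format = "g", digits = 6) else as.character(x)
}

#' Export a pipeline report to files
#'
#' Writes six files with stable formatting (numbers at 6 significant digits,
#' so re-exporting an identical report reproduces identical bytes):
#' `descriptive.csv`, `tests.json`, `confusion.csv`, `distances.csv`,
#' `dendrogram.nwk` and `summary.txt`. Reports whose discriminant stages were
#' skipped mark them "skipped" in `tests.json`.
#'
#' @param report a `pipeline_report`.
#' @param dir output directory (created if missing).
#' @return character vector of the written paths, invisibly.
#' @export
export_report <- function(report, dir) {
  stopifnot(inherits(report, "pipeline_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (file.access(dir, 2) != 0) stop("directory not writable: ", dir)
  paths <- character(0)
  wf <- function(name) { p <- file.path(dir, name); paths <<- c(paths, p); p }

  d <- report$descriptive
  d[-1] <- lapply(d[-1], .fmt6)
  utils::write.csv(d, wf("descriptive.csv"), row.names = FALSE, quote = FALSE)

  tj <- if (is.null(report$tests)) list(status = "skipped", notices = report$notices)
  else list(status = "ok",
            wilks = report$tests$wilks,
            bartlett = report$tests$bartlett,
            pillai = report$tests$pillai,
            eigenvalues = report$cda$lambda,
            percent_discrimination = report$cda$percent_discrimination,
            canonical_correlations = report$cda$canonical_correlation)
  writeLines(jsonlite::toJSON(tj, auto_unbox = TRUE, digits = 6, dataframe = "rows"),
             wf("tests.json"))

  if (!is.null(report$classification)) {
    cm <- as.data.frame.matrix(report$classification$confusion)
    cm <- cbind(prior = rownames(cm), cm)
    utils::write.csv(cm, wf("confusion.csv"), row.names = FALSE, quote = FALSE)
  } else writeLines("skipped", wf("confusion.csv"))

  if (!is.null(report$distances)) {
    dm <- as.data.frame(apply(report$distances, 2, .fmt6))
    dm <- cbind(group = rownames(report$distances), dm)
    utils::write.csv(dm, wf("distances.csv"), row.names = FALSE, quote = FALSE)
  } else writeLines("skipped", wf("distances.csv"))

  writeLines(if (!is.null(report$dendrogram)) report$dendrogram$newick else "skipped;",
             wf("dendrogram.nwk"))

  con <- textConnection("out", "w", local = TRUE)
  sink(con); print(report); sink()
  close(con)
  writeLines(c(out,
               paste0("config_hash: ", report$provenance$config_hash),
               paste0("pedigree_hash: ", report$provenance$pedigree_hash),
               paste0("version: ", report$provenance$package_version)),
             wf("summary.txt"))
  invisible(paths)
}
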