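# Pipeline orchestration: simulate -> classify -> noise -> introns -> models
# as one seeded, manifest-tracked run, plus the model-layer assembly used by
# both the pipeline and the analysis scripts.

FEATURE_COLS <- c("gene_length", "lethal", "kaks", "module_size",
                  "alpha_wgd", "betagamma_wgd", "breadth", "tandem")

#' Assemble the gene-level modelling table
#'
#' Joins the noise table, consensus methylation calls and the genomic
#' feature table; keeps genes with a consensus gbM or unmethylated label and
#' complete features (listwise deletion), and encodes gbM as 0/1.
#'
#' @param noise_tbl Noise table (from \code{\link{noise_table}}\code{$table}).
#' @param calls Consensus calls (\code{gene_id}, \code{class}) -- e.g. from
#'   \code{\link{consensus_call}} or planted truth.
#' @param features Feature table from \code{\link{simulate_features}} or file.
#' @return Data.frame with noise measures, features, \code{class} and
#'   \code{gbM}.
#' @export
assemble_model_data <- function(noise_tbl, calls, features) {
  d <- merge(noise_tbl, calls[!is.na(calls$class) &
                                calls$class %in% c("gbM", "unmethylated"), ],
             by = "gene_id")
  d <- merge(d, features, by = "gene_id")
  d <- d[complete.cases(d), , drop = FALSE]
  d$gbM <- as.integer(d$class == "gbM")
  d
}

#' ANCOVA + BIC model averaging for a noise or consistency response
#'
#' Follows the published procedure: greedy log-transform selection (mean
#' expression exempt when the response is F*), centring/scaling of all
#' variables (binary indicators included), all-subsets BIC model averaging
#' over gbM plus the genomic features, and a Type II ANCOVA refit of the
#' minimum-BIC model.
#'
#' @param data Output of \code{\link{assemble_model_data}}.
#' @param response One of \code{"fstar"}, \code{"fprime"},
#'   \code{"consistency"}.
#' @param extra_predictors Additional predictor columns beyond gbM and the
#'   standard feature set.
#' @return List: \code{averaged} (\code{averaged_model}), \code{best_fit}
#'   (\code{model_fit} of the best model, \code{NULL} if intercept-only),
#'   \code{transforms}, \code{n}.
#' @export
noise_model_analysis <- function(data, response = c("fstar", "fprime",
                                                    "consistency"),
                                 extra_predictors = character()) {
  response <- match.arg(response)
  predictors <- c("gbM", "mu", FEATURE_COLS, extra_predictors)
  d <- data[complete.cases(data[c(response, predictors)]), , drop = FALSE]
  tr <- choose_transforms(d, response, predictors,
                          response_is_fstar = (response == "fstar"),
                          mean_expression = "mu")
  d <- standardize(tr$data, c(response, predictors))
  avg <- bic_model_average(d, response, predictors)
  best_fit <- if (length(avg$best)) fit_ancova(d, response, avg$best) else NULL
  list(averaged = avg, best_fit = best_fit, transforms = tr$transforms,
       n = nrow(d))
}

#' ANCOVA + BIC model averaging for intron FPKM
#'
#' Response is log(intron FPKM + 1) over genes carrying at least one intron;
#' candidate predictors are gbM, the total (gene) FPKM, gene length, total
#' intron length, intron number and the genomic features, with the same
#' transform selection and centring/scaling as the noise models.
#'
#' @param intron_rows Filtered rows from \code{\link{intron_fpkm_table}}.
#' @param model_data Output of \code{\link{assemble_model_data}} (supplies
#'   class labels and features).
#' @return As \code{\link{noise_model_analysis}}.
#' @export
intron_model_analysis <- function(intron_rows, model_data) {
  keep <- c("gene_id", "class", "gbM", FEATURE_COLS)
  d <- merge(intron_rows[intron_rows$intron_number > 0, , drop = FALSE],
             model_data[, setdiff(keep, "gene_length")], by = "gene_id")
  d$log_intron_fpkm <- log1p(d$intron_FPKM)
  predictors <- c("gbM", "total_FPKM", "gene_length", "total_intron_length",
                  "intron_number", setdiff(FEATURE_COLS, "gene_length"))
  d <- d[complete.cases(d[c("log_intron_fpkm", predictors)]), , drop = FALSE]
  tr <- choose_transforms(d, "log_intron_fpkm", predictors)
  d <- standardize(tr$data, c("log_intron_fpkm", predictors))
  avg <- bic_model_average(d, "log_intron_fpkm", predictors)
  best_fit <- if (length(avg$best)) {
    fit_ancova(d, "log_intron_fpkm", avg$best)
  } else NULL
  list(averaged = avg, best_fit = best_fit, transforms = tr$transforms,
       n = nrow(d))
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full synthetic pipeline
#'
#' Executes simulate -> classify -> noise -> introns -> models in order,
#' writing every intermediate as plain text under \code{outdir} and
#' returning a manifest of md5 digests. Every source of randomness derives
#' from \code{config$seed}, so a rerun with the same config reproduces
#' byte-identical outputs.
#'
#' @param config A \code{\link{sim_config}}.
#' @param outdir Output directory (created if needed).
#' @return List with \code{manifest} and the in-memory stage \code{results}.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)

  genes <- stage("simulate", {
    if (config$n_genes <= 0) stop("n_genes must be positive")
    g <- simulate_genome(config)
    write_gff3(g, p("annotation.gff3"))
    g
  })
  sim <- stage("simulate", {
    meth <- simulate_methylomes(config, genes)
    write_cytosine_report(meth$replicates[[1]], p("methylome_rep1.tsv"))
    write_cytosine_report(meth$replicates[[2]], p("methylome_rep2.tsv"))
    write_tsv_table(meth$truth, p("ground_truth.tsv"))
    mat <- simulate_expression(config, meth$truth)
    write_fpkm_matrix(mat, p("fpkm.tsv"))
    feats <- simulate_features(config, meth$truth)
    write_tsv_table(feats, p("features.tsv"))
    reads <- simulate_reads(config, genes, mat, meth$truth)
    write_bed_reads(reads, p("reads.bed"))
    list(truth = meth$truth, mat = mat, feats = feats, reads = reads)
  })

  calls <- stage("classify", {
    models <- parse_gff3(p("annotation.gff3"))
    rep1 <- parse_cytosine_report(p("methylome_rep1.tsv"), "cx")
    rep2 <- parse_cytosine_report(p("methylome_rep2.tsv"), "cx")
    c1 <- classify_genes(summarize_gene_methylation(rep1, models))
    c2 <- classify_genes(summarize_gene_methylation(rep2, models))
    cons <- consensus_call(c1, c2)
    out <- data.frame(gene_id = c1$gene_id, class_rep1 = c1$class,
                      class_rep2 = c2$class, consensus = cons$class,
                      p_CG_rep1 = c1$p_CG, p_CHG_rep1 = c1$p_CHG,
                      p_CHH_rep1 = c1$p_CHH, stringsAsFactors = FALSE)
    write_tsv_table(out, p("methylation_calls.tsv"))
    list(rep1 = c1, rep2 = c2, consensus = cons, models = models)
  })

  noise <- stage("noise", {
    mat <- read_fpkm_matrix(p("fpkm.tsv"))
    nt <- noise_table(mat)
    write_tsv_table(nt$table, p("noise.tsv"))
    jsonlite::write_json(
      list(degree = nt$model$degree,
           coefficients = nt$model$coefficients,
           kendall_tau = nt$model$tau, kendall_p = nt$model$tau_p,
           decorrelated = !nt$model$warning),
      p("variance_model.json"), auto_unbox = TRUE, digits = NA)
    nt
  })

  introns <- stage("introns", {
    nonov <- flag_overlapping_genes(calls$models)
    derive_introns(nonov, p("annotation_introns_as_exons.gff3"))
    reads <- read_bed_reads(p("reads.bed"))
    rows <- count_reads(reads, nonov)
    rows <- intron_fpkm_table(rows, library_fragments = length(reads))
    write_tsv_table(rows, p("intron_counts.tsv"))
    filter_intron_genes(rows)
  })

  models_out <- stage("models", {
    cons <- calls$consensus
    md <- assemble_model_data(noise$table, cons, sim$feats)
    tab1 <- group_comparison_table(
      md, c("fstar", "fprime", "consistency", "mu", "gene_length", "lethal",
            "kaks", "module_size", "breadth", "alpha_wgd", "betagamma_wgd",
            "tandem"))
    write_tsv_table(tab1, p("table1_group_comparison.tsv"))
    fits <- list(fstar = noise_model_analysis(md, "fstar"),
                 fprime = noise_model_analysis(md, "fprime"),
                 consistency = noise_model_analysis(md, "consistency"),
                 intron = intron_model_analysis(introns, md))
    for (nm in names(fits)) {
      bf <- fits[[nm]]$best_fit
      if (!is.null(bf)) {
        tab <- merge(data.frame(term = names(bf$coefficients),
                                coefficient = unname(bf$coefficients)),
                     bf$anova, by = "term", all.x = TRUE)
        write_tsv_table(tab, p(paste0("best_model_", nm, ".tsv")))
      }
      imp <- fits[[nm]]$averaged$importance
      write_tsv_table(data.frame(term = names(imp), importance = unname(imp),
                                 in_best = names(imp) %in% fits[[nm]]$averaged$best),
                      p(paste0("importance_", nm, ".tsv")))
    }
    cand <- gbm_prediction_candidates(md, introns)
    gbm_pred <- predict_gbm_model(standardize(cand),
                                  setdiff(names(cand), "gbM"),
                                  gbm_col = "gbM")
    write_tsv_table(data.frame(term = names(gbm_pred$model$importance),
                               importance = unname(gbm_pred$model$importance),
                               in_best = names(gbm_pred$model$importance) %in%
                                 gbm_pred$model$best),
                    p("gbm_prediction_model.tsv"))
    list(table1 = tab1, fits = fits, gbm_prediction = gbm_pred,
         model_data = md)
  })

  files <- list.files(outdir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$|report\\.txt$", files)]
  manifest <- list(
    version = as.character(utils::packageVersion("gbmnoise")),
    seed = config$seed,
    n_genes = config$n_genes, n_cells = config$n_cells,
    digests = as.list(setNames(unname(tools::md5sum(files)),
                               basename(files))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(manifest = manifest,
       results = list(sim = sim, calls = calls, noise = noise,
                      introns = introns, models = models_out))
}

#' Candidate table for the gbM-prediction regression
#'
#' Assembles, on the appropriate scales, every measure that could predict
#' gbM: the noise measures, consistency, expression level, the genomic
#' features and the intron covariates. Log scales are applied to skewed
#' positive variables.
#'
#' @param model_data Output of \code{\link{assemble_model_data}}.
#' @param intron_rows Rows from \code{\link{intron_fpkm_table}}.
#' @return Data.frame with a 0/1 \code{gbM} column and candidate features.
#' @export
gbm_prediction_candidates <- function(model_data, intron_rows) {
  d <- merge(model_data,
             intron_rows[, c("gene_id", "intron_FPKM", "total_intron_length",
                             "intron_number")], by = "gene_id")
  out <- data.frame(gbM = d$gbM, fstar = d$fstar, fprime = d$fprime,
                    consistency = d$consistency, mu = log(d$mu),
                    gene_length = log(d$gene_length),
                    total_intron_length = log1p(d$total_intron_length),
                    intron_number = d$intron_number,
                    intron_fpkm = log1p(d$intron_FPKM),
                    lethal = d$lethal, kaks = log(d$kaks),
                    module_size = log(d$module_size),
                    alpha_wgd = d$alpha_wgd, betagamma_wgd = d$betagamma_wgd,
                    breadth = d$breadth, tandem = d$tandem)
  out[complete.cases(out), , drop = FALSE]
}

#' Summarise a completed pipeline run
#'
#' Renders, from the files a run wrote, a plain-text report: gene counts per
#' methylation class, the distribution of expression consistency split by
#' class (proportions per bin summing to 1), group medians, and the fitted
#' model tables. A missing stage output is marked absent rather than
#' raising.
#'
#' @param outdir Directory of a \code{\link{run_pipeline}} run.
#' @param path Optional path for the text report (default
#'   \code{outdir/report.txt}).
#' @return Invisibly, a list with the report sections.
#' @export
summarize_run <- function(outdir, path = file.path(outdir, "report.txt")) {
  sections <- list()
  lines <- character()
  add <- function(...) lines <<- c(lines, ...)
  have <- function(f) file.exists(file.path(outdir, f))

  add("== gbmnoise run summary ==", "")
  if (have("methylation_calls.tsv")) {
    calls <- read_tsv_table(file.path(outdir, "methylation_calls.tsv"))
    cons <- ifelse(is.na(calls$consensus) | calls$consensus == "",
                   "other", calls$consensus)
    tab <- table(cons)
    sections$class_counts <- tab
    add("[methylation classes, replicate consensus]",
        paste(names(tab), as.integer(tab), sep = ": "), "")
  } else add("[methylation classes] absent", "")

  if (have("noise.tsv") && have("methylation_calls.tsv")) {
    noise <- read_tsv_table(file.path(outdir, "noise.tsv"))
    calls <- read_tsv_table(file.path(outdir, "methylation_calls.tsv"))
    cl <- calls$consensus[match(noise$gene_id, calls$gene_id)]
    grp <- ifelse(is.na(cl) | cl == "", "other", cl)
    bins <- table(factor(grp, levels = c("gbM", "unmethylated", "other")),
                  noise$consistency)
    prop <- prop.table(bins, margin = 2)
    sections$consistency_by_class <- prop
    add("[proportion of classes among genes expressed in n cells]",
        utils::capture.output(print(round(prop, 3))), "")
  } else add("[expression consistency histogram] absent", "")

  if (have("table1_group_comparison.tsv")) {
    tab1 <- read_tsv_table(file.path(outdir, "table1_group_comparison.tsv"))
    sections$table1 <- tab1
    add("[group comparison, gbM vs unmethylated]",
        utils::capture.output(print(tab1, digits = 3)), "")
  } else add("[group comparison] absent", "")

  for (nm in c("fstar", "fprime", "consistency", "intron")) {
    f <- paste0("best_model_", nm, ".tsv")
    if (have(f)) {
      tab <- read_tsv_table(file.path(outdir, f))
      sections[[paste0("best_", nm)]] <- tab
      add(paste0("[best model: ", nm, "]"),
          utils::capture.output(print(tab, digits = 3)), "")
    } else add(paste0("[best model: ", nm, "] absent"), "")
  }

  if (have("gbm_prediction_model.tsv")) {
    tab <- read_tsv_table(file.path(outdir, "gbm_prediction_model.tsv"))
    sections$gbm_prediction <- tab
    add("[gbM prediction model]",
        utils::capture.output(print(tab, digits = 3)), "")
  } else add("[gbM prediction model] absent", "")

  writeLines(lines, path)
  invisible(sections)
}
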