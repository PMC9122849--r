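# End-to-end orchestration: load -> diet weights / cover shares -> index ->
# contributions -> seed-set response -> standardization -> AICc selections
# per mapping approach -> approach comparison -> landscape regressions ->
# structured run report.

periods_present <- function(diet) {
  pres <- intersect(fai_periods(), unique(diet$period))
  if (length(pres) > 0L) c(pres, "pooled") else character(0)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a validated bundle (or a directory of CSV inputs)
#' and returns a structured, versioned run report. Periods are those present
#' in the diet table plus the pooled season. The model-selection stage needs
#' at least 5 landscapes with a seed-set response (AICc requires
#' `n - k - 1 > 0` for the single-predictor candidates); with fewer, the
#' stage is skipped with a notice in `$warnings`.
#'
#' @param input An `fai_bundle` or a directory path for [load_tables()].
#' @param include_distances Include distances in the fine land-cover pool.
#' @param max_size Largest subset size in the selections.
#' @param vr_include_unmapped See [fai_table()].
#' @param include_zero_pods See [seeds_per_pod()].
#' @return List of class `fai_run_report`: `schema_version`, `config`,
#'   `input_summary`, `fai` (long table), `fai_summary`, `contributions`,
#'   `response`, `selections`, `comparison`, `landscape_regressions`,
#'   `correlations`, `warnings`.
#' @export
run_all <- function(input, include_distances = TRUE, max_size = Inf,
                    vr_include_unmapped = FALSE, include_zero_pods = FALSE) {
  warnings <- character(0)
  note <- function(msg) warnings[[length(warnings) + 1L]] <<- msg

  if (is.character(input)) {
    digests <- tryCatch(
      as.list(tools::md5sum(list.files(input, full.names = TRUE,
                                       pattern = "\\.csv$"))),
      error = function(e) list())
    bundle <- load_tables(input)
  } else {
    bundle <- input
    digests <- list()
  }
  stopifnot(inherits(bundle, "fai_bundle"))
  input_summary <- lapply(
    bundle[c("diet", "plants", "cover", "landcover", "distances", "seedset")],
    nrow)

  periods <- periods_present(bundle$diet)
  fai_tab <- withCallingHandlers(
    fai_table(bundle, periods = periods,
              vr_include_unmapped = vr_include_unmapped),
    message = function(m) { note(conditionMessage(m)); invokeRestart("muffleMessage") })
  fai_summary <- do.call(rbind, lapply(periods, function(t) {
    v <- fai_tab$fai[fai_tab$period == t]
    data.frame(period = t, mean = mean(v), sd = stats::sd(v),
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  }))

  contributions <- do.call(rbind, unlist(recursive = FALSE, lapply(
    periods, function(t) lapply(c("origin", "growth_form"), function(gk)
      suppressMessages(contribution_breakdown(
        bundle, t, gk, vr_include_unmapped = vr_include_unmapped))))))

  response <- withCallingHandlers(
    seeds_per_pod(bundle$seedset, include_zero_pods = include_zero_pods),
    warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
  composition <- landscape_composition(bundle$landcover, bundle$distances)

  n_resp <- sum(!is.na(response$seeds_per_pod))
  selections <- comparison <- NULL
  regressions <- correlations <- NULL
  if (n_resp >= 5L && all(c("preceding", "synchronous") %in% periods)) {
    cmp <- withCallingHandlers(
      approach_comparison(response, fai_tab, composition,
                          include_distances = include_distances,
                          max_size = max_size),
      warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
    selections <- cmp$selections
    comparison <- cmp$comparison
  } else {
    note(paste0("model selection skipped: needs >= 5 landscapes with a ",
                "response and both seasonal periods (have n = ", n_resp, ")"))
  }
  if (nrow(composition) >= 3L) {
    lr <- landscape_fai_regressions(fai_tab, composition)
    regressions <- lr$regressions
    correlations <- lr$correlations
  } else {
    note("landscape regressions skipped: fewer than 3 landscapes")
  }

  structure(list(
    schema_version = "1.0",
    config = list(include_distances = include_distances,
                  max_size = max_size,
                  vr_include_unmapped = vr_include_unmapped,
                  include_zero_pods = include_zero_pods,
                  periods = periods),
    input_summary = input_summary, input_digests = digests,
    fai = fai_tab, fai_summary = fai_summary,
    contributions = contributions, response = response,
    composition = composition,
    selections = selections, comparison = comparison,
    landscape_regressions = regressions, correlations = correlations,
    warnings = warnings
  ), class = "fai_run_report")
}

#' @export
print.fai_run_report <- function(x, ...) {
  cat("floravail run report (schema", x$schema_version, ")\n")
  cat("periods:", paste(x$config$periods, collapse = ", "), "\n")
  print(transform(x$fai_summary, mean = round(mean, 4), sd = round(sd, 3),
                  min = round(min, 3), max = round(max, 3)), row.names = FALSE)
  if (!is.null(x$comparison)) {
    cat("\nmost parsimonious model per approach:\n")
    print(transform(x$comparison, r2_mult = round(r2_mult, 3),
                    r2_adj = round(r2_adj, 3), aicc = round(aicc, 2)),
          row.names = FALSE)
  }
  if (length(x$warnings) > 0L) {
    cat("\nnotes:\n"); for (w in x$warnings) cat(" -", w, "\n")
  }
  invisible(x)
}

#' Write the run report to CSV files and a JSON document
#'
#' Emits `fai.csv`, `contributions.csv`, `selection_table.csv` (Table-1
#' style: one row per retained model x predictor), `comparison.csv`,
#' `regressions.csv`, `correlations.csv` and `run_report.json`. CSV numbers
#' are rounded to 4 significant decimals; the JSON keeps full precision.
#'
#' @param report `fai_run_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  round4 <- function(df) {
    for (j in seq_along(df)) if (is.numeric(df[[j]])) df[[j]] <- round(df[[j]], 4)
    df
  }
  utils::write.csv(round4(report$fai), file.path(dir, "fai.csv"),
                   row.names = FALSE)
  utils::write.csv(round4(report$contributions),
                   file.path(dir, "contributions.csv"), row.names = FALSE)
  if (!is.null(report$selections)) {
    sel <- do.call(rbind, lapply(names(report$selections), function(nm) {
      s <- report$selections[[nm]]
      tab <- s$table[s$table$retained, ]
      coefs <- selection_coefficients(s)
      merged <- merge(
        data.frame(method = nm, tab[, c("model", "df", "r2_mult", "r2_adj",
                                        "aicc", "delta", "weight")]),
        coefs, by = "model", all.x = TRUE)
      merged[order(merged$delta), ]
    }))
    utils::write.csv(round4(sel), file.path(dir, "selection_table.csv"),
                     row.names = FALSE)
    utils::write.csv(round4(report$comparison),
                     file.path(dir, "comparison.csv"), row.names = FALSE)
  }
  if (!is.null(report$landscape_regressions)) {
    utils::write.csv(round4(report$landscape_regressions),
                     file.path(dir, "regressions.csv"), row.names = FALSE)
    utils::write.csv(round(report$correlations, 4),
                     file.path(dir, "correlations.csv"))
  }
  json <- report
  json$selections <- lapply(json$selections, `[[`, "table")
  json$correlations <- if (!is.null(json$correlations)) {
    as.data.frame(json$correlations)
  }
  jsonlite::write_json(json, file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}

#' Reproduce the original field-study analysis from a local data deposit
#'
#' The deposited field data are never downloaded automatically. Point
#' `deposit_dir` at a local copy whose tables have been mapped to the input
#' schemas (optionally via a key-value `mapping` file with entries like
#' `cover.landscape_id = SiteID` renaming deposit columns). When the deposit
#' is absent the function returns a skipped-with-notice status instead of
#' failing. When a `reference` table of published statistics
#' (columns `quantity`, `value`) is supplied, a side-by-side computed vs
#' published table is added for the quantities this function computes:
#' `preceding_r2_mult`, `urban_r2_adj`, `preceding_arable_r2`,
#' `preceding_arable_r`.
#'
#' @param deposit_dir Directory with the mapped deposit tables.
#' @param reference Optional data.frame (or CSV path) of published values.
#' @param mapping Optional key-value file of column renames.
#' @return For an absent deposit, `list(status = "skipped", notice = ...)`;
#'   otherwise `list(status = "ok", report, computed, side_by_side)`.
#' @export
reproduce_study <- function(deposit_dir, reference = NULL, mapping = NULL) {
  if (is.null(deposit_dir) || !dir.exists(deposit_dir) ||
      length(list.files(deposit_dir, pattern = "\\.csv$")) == 0L) {
    return(list(status = "skipped",
                notice = paste0("data deposit not found at '",
                                if (is.null(deposit_dir)) "<NULL>" else deposit_dir,
                                "'; download it manually and map its tables ",
                                "to the input schemas to run the reproduction")))
  }
  tabs <- lapply(stats::setNames(nm = c("diet", "plants", "cover", "landcover",
                                        "distances", "seedset")),
                 function(tb) utils::read.csv(file.path(deposit_dir,
                                                        paste0(tb, ".csv")),
                                              comment.char = "#",
                                              stringsAsFactors = FALSE))
  if (!is.null(mapping)) {
    map <- read_config(mapping)
    for (key in names(map)) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
      if (length(parts) != 2L || !parts[1L] %in% names(tabs)) {
        stop("mapping: cannot interpret key '", key,
             "' (expected <table>.<standard_column> = <deposit_column>)",
             call. = FALSE)
      }
      tb <- parts[1L]; std <- parts[2L]; from <- as.character(map[[key]])
      if (!from %in% names(tabs[[tb]])) {
        stop("mapping: deposit table '", tb, "' has no column '", from, "'",
             call. = FALSE)
      }
      names(tabs[[tb]])[names(tabs[[tb]]) == from] <- std
    }
  }
  bundle <- as_bundle(tabs$diet, tabs$plants, tabs$cover, tabs$landcover,
                      tabs$distances, tabs$seedset)
  report <- run_all(bundle)

  comp <- report$composition[order(report$composition$landscape_id), ]
  resp <- report$response
  y <- resp$seeds_per_pod[match(comp$landscape_id, resp$landscape_id)]
  fai_pre <- with(report$fai[report$fai$period == "preceding", ],
                  fai[match(comp$landscape_id, landscape_id)])
  ok <- !is.na(y)
  pre_fit <- fit_ols(y[ok], cbind(preceding = standardize_2sd(fai_pre[ok])),
                     response = "seeds_per_pod")
  urb_fit <- fit_ols(y[ok], cbind(urban = standardize_2sd(comp$urban[ok])),
                     response = "seeds_per_pod")
  pa_fit <- fit_ols(fai_pre, cbind(arable = comp$arable),
                    response = "fai_preceding")
  computed <- data.frame(
    quantity = c("preceding_r2_mult", "urban_r2_adj", "preceding_arable_r2",
                 "preceding_arable_r"),
    computed = c(pre_fit$r2_mult, urb_fit$r2_adj, pa_fit$r2_mult,
                 stats::cor(fai_pre, comp$arable)),
    stringsAsFactors = FALSE)
  side_by_side <- NULL
  if (!is.null(reference)) {
    if (is.character(reference)) {
      reference <- utils::read.csv(reference, stringsAsFactors = FALSE)
    }
    side_by_side <- merge(computed, reference[, c("quantity", "value")],
                          by = "quantity", all.x = TRUE)
    names(side_by_side)[names(side_by_side) == "value"] <- "published"
    side_by_side$difference <- side_by_side$computed - side_by_side$published
  }
  list(status = "ok", report = report, computed = computed,
       side_by_side = side_by_side)
}
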