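#' Write the deterministic analysis report
#'
#' Runs [run_cea()] and writes plain delimited tables: per-strategy totals
#' (CN Yuan and USD), pairwise comparisons with dominance/ICER labels, one
#' long-format trace export per strategy, and a JSON run manifest recording
#' the config hash, seed-free determinism and the output file list.
#'
#' @param config_path Path to a YAML configuration file.
#' @param out_dir Output directory (created if missing).
#' @param wtp Willingness-to-pay threshold; default from the config.
#' @return Invisibly, the manifest as a list. Errors (nonzero status under
#'   the CLI) on invalid config or unwritable output.
#' @export
write_cea_report <- function(config_path, out_dir, wtp = NULL) {
  config <- load_config(config_path)
  if (is.null(wtp)) wtp <- config$settings$wtp_thresholds[1]
  ensure_dir(out_dir)
  res <- run_cea(config, wtp)

  tab <- tidy(res)
  tab$total_cost_usd <- to_usd(tab$total_cost_cny, config$settings)
  tab$incr_cost_usd <- to_usd(tab$incr_cost_cny, config$settings)
  files <- character()
  files <- c(files, write_tsv(tab, file.path(out_dir, "strategy_results.tsv")))
  files <- c(files, write_tsv(
    dplyr::bind_rows(lapply(res$comparisons, tidy)),
    file.path(out_dir, "comparisons.tsv")))
  for (st in config$strategies) {
    tr <- run_cohort(config, st)
    files <- c(files, write_tsv(
      tidy(tr), file.path(out_dir, sprintf("trace_%s.tsv", st$name))))
  }
  write_manifest(out_dir, config_path, "run", seed = NA, files = files)
}

#' Write the one-way sensitivity (tornado) report
#'
#' @inheritParams write_cea_report
#' @param reference,comparator Strategy names.
#' @return Invisibly, the manifest list.
#' @export
write_owsa_report <- function(config_path, out_dir, wtp = NULL,
                              reference = NULL, comparator = NULL) {
  config <- load_config(config_path)
  if (is.null(wtp)) wtp <- config$settings$wtp_thresholds[1]
  if (is.null(reference)) reference <- config$strategies[[1]]$name
  if (is.null(comparator)) comparator <- config$strategies[[2]]$name
  ensure_dir(out_dir)
  ow <- run_owsa(config, reference, comparator, wtp)
  files <- c(
    write_tsv(as_tibble(ow), file.path(out_dir, "owsa.tsv")),
    write_tsv(utils::head(as_tibble(ow), 10), file.path(out_dir, "owsa_top10.tsv")))
  write_manifest(out_dir, config_path, "owsa", seed = NA, files = files)
}

#' Write the probabilistic sensitivity report
#'
#' PSA draw-level results plus the cost-effectiveness acceptability table on
#' a willingness-to-pay grid from 0 to the highest configured threshold,
#' always including every configured threshold exactly.
#'
#' @inheritParams write_cea_report
#' @param n_iterations Monte-Carlo iterations (study default 5,000).
#' @param seed Master RNG seed.
#' @return Invisibly, the manifest list.
#' @export
write_psa_report <- function(config_path, out_dir, n_iterations = 5000,
                             seed = 1L) {
  config <- load_config(config_path)
  ensure_dir(out_dir)
  psa <- run_psa(config, n_iterations, seed)
  thr <- config$settings$wtp_thresholds
  grid <- sort(unique(c(seq(0, max(thr), length.out = 31), thr)))
  cc <- ceac(psa, grid)
  files <- c(
    write_tsv(psa$samples, file.path(out_dir, "psa_results.tsv")),
    write_tsv(psa$draws, file.path(out_dir, "psa_draws.tsv")),
    write_tsv(as_tibble(cc), file.path(out_dir, "ceac.tsv")))
  write_manifest(out_dir, config_path, "psa", seed = seed, files = files)
}

ensure_dir <- function(d) {
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  probe <- file.path(d, ".write_probe")
  ok <- tryCatch({ writeLines("", probe); file.remove(probe); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop(sprintf("output directory '%s' is not writable", d), call. = FALSE)
  invisible(d)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_manifest <- function(out_dir, config_path, subcommand, seed, files) {
  manifest <- list(
    subcommand = subcommand,
    config_path = config_path,
    config_md5 = unname(tools::md5sum(config_path)),
    seed = if (is.na(seed)) NULL else seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("szcea")),
    outputs = basename(files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
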