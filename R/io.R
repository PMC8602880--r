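# Run serialization: JSON transcript + CSV belief arrays, and the
# command-line entry point.

#' Write a run to disk
#'
#' Serializes a hierarchical run as plain-text artifacts: `transcript.json`
#' (epochs, heard/spoken tokens, actions, MAP locations), `beliefs_level1.csv`
#' and `beliefs_level2.csv` (rows = factor levels, columns = time steps,
#' mirroring a belief raster), and `run_log.txt` (a configuration echo).
#'
#' @param record A `"hier_record"` from [run_hierarchy()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run <- function(record, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tx <- as_transcript(record)
  js <- jsonlite::toJSON(unclass(tx), digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
  writeLines(js, file.path(dir, "transcript.json"))
  utils::write.csv(beliefs_level1_frame(record),
                   file.path(dir, "beliefs_level1.csv"), row.names = FALSE)
  utils::write.csv(beliefs_level2_frame(record),
                   file.path(dir, "beliefs_level2.csv"), row.names = FALSE)
  cfg <- record$model$config
  writeLines(c("deepexplain run log",
               paste0("epochs: ", paste(cfg$epochs, collapse = ",")),
               paste0("query_type: ", cfg$query_type),
               paste0("true_context: ", cfg$true_context),
               paste0("kappa: ", cfg$kappa),
               paste0("link_smoothing: ", cfg$link_smoothing),
               paste0("seed: ", cfg$seed)),
             file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Level-1 belief raster of a run
#'
#' @param record A `"hier_record"`.
#' @return Data frame with one row per (factor, level) and one column per
#'   global time step (epochs concatenated), holding the policy-averaged
#'   posterior probability assigned to that level at that step.
#' @export
beliefs_level1_frame <- function(record) {
  m1 <- record$model$level1
  rows <- unlist(lapply(names(m1$factors), function(f) {
    paste0(f, ":", m1$factors[[f]])
  }))
  cols <- list()
  for (er in record$epochs) {
    for (t in seq_along(er$trial$beliefs)) {
      cols[[paste0("e", er$epoch, "_t", t)]] <-
        unlist(er$trial$beliefs[[t]], use.names = FALSE)
    }
  }
  cbind(data.frame(state = rows, stringsAsFactors = FALSE),
        as.data.frame(cols))
}

#' Level-2 belief raster of a run
#'
#' @param record A `"hier_record"`.
#' @return Data frame with one row per (factor, level) and one column per
#'   epoch, holding the end-of-epoch level-2 posterior.
#' @export
beliefs_level2_frame <- function(record) {
  f2 <- record$model$level2$factors
  rows <- unlist(lapply(names(f2), function(f) paste0(f, ":", f2[[f]])))
  cols <- list()
  for (er in record$epochs) {
    cols[[paste0("epoch", er$epoch)]] <-
      unlist(er$level2_posterior, use.names = FALSE)
  }
  cbind(data.frame(state = rows, stringsAsFactors = FALSE),
        as.data.frame(cols))
}

#' Command-line entry point
#'
#' Thin argument-parsing wrapper around [run_standard()] and
#' [run_confabulation()]; invoked by the shipped
#' `inst/cli/deepexplain-run.R` script as
#' `Rscript deepexplain-run.R --mode standard --query second
#' --context right --seed 1 --out DIR`.
#'
#' @param args Character vector of command-line arguments
#'   (default `commandArgs(trailingOnly = TRUE)`).
#' @return Invisibly, the output directory.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  opt <- list(mode = "standard", query = "second", context = "right",
              seed = "1", out = "deepexplain-out", config = NA)
  i <- 1L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt)) stop("unknown option: ", args[i], call. = FALSE)
    opt[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  cfg <- NULL
  if (!is.na(opt$config)) {
    raw <- jsonlite::fromJSON(opt$config, simplifyVector = TRUE)
    cfg <- do.call(task_config, raw)
  }
  seed <- as.integer(opt$seed)
  res <- switch(match.arg(opt$mode, c("standard", "confabulation")),
                standard = run_standard(opt$query, opt$context, seed,
                                        config = cfg),
                confabulation = run_confabulation(seed, opt$query,
                                                  config = cfg))
  write_run(res$record, opt$out)
  print(res$transcript)
  if (!is.null(res$verdicts)) {
    for (nm in names(res$verdicts)) {
      cat(nm, ": ",
          if (res$verdicts[[nm]]$consistent) "consistent" else "inconsistent",
          "\n", sep = "")
    }
  }
  invisible(opt$out)
}
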