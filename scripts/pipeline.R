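#!/usr/bin/env Rscript
# Thin shell wrapper over the ramanpls pipeline commands.
#
#   Rscript scripts/pipeline.R simulate  --config cfg.yaml --out-dir out [--seed N]
#   Rscript scripts/pipeline.R calibrate --spectra a.csv,b.csv --references ra.csv,rb.csv --out-dir out
#   Rscript scripts/pipeline.R predict   --model model.json --spectra s.csv --out pred.csv
#   Rscript scripts/pipeline.R evaluate  --predictions pred.csv --references r.csv --out report.csv
#   Rscript scripts/pipeline.R transfer  --out-dir out [--seed N]
#
# Flags: --config, --seed, --out-dir, --log-level (debug|info|warn|error).

suppressMessages(library(ramanpls))
`%||%` <- function(a, b) if (is.null(a)) b else a

args <- commandArgs(trailingOnly = TRUE)
if (length(args) < 1) stop("usage: pipeline.R <command> [flags]")
command <- args[1]
flags <- list(`log-level` = "info", `out-dir` = ".")
i <- 2
while (i <= length(args)) {
  key <- sub("^--", "", args[i])
  flags[[key]] <- args[i + 1]
  i <- i + 2
}
seed <- if (!is.null(flags$seed)) as.integer(flags$seed)
split_csv <- function(x) strsplit(x, ",")[[1]]

status <- tryCatch({
  switch(command,
    simulate = cmd_simulate(flags$config, flags$`out-dir`, seed,
                            flags$`log-level`),
    calibrate = cmd_calibrate(split_csv(flags$spectra),
                              split_csv(flags$references), flags$`out-dir`,
                              seed = seed %||% 20220726,
                              log_level = flags$`log-level`),
    predict = cmd_predict(flags$model, flags$spectra,
                          flags$out %||% "predictions.csv",
                          log_level = flags$`log-level`),
    evaluate = cmd_evaluate(flags$predictions, flags$references,
                            flags$out %||% "evaluation_report.csv"),
    transfer = cmd_transfer_experiment(list(), flags$`out-dir`,
                                       seed %||% 20220726,
                                       flags$`log-level`),
    stop("unknown command: ", command)
  )
  0L
}, error = function(e) {
  message("error: ", conditionMessage(e))
  1L
})
quit(status = status)
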