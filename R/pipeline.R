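# Pipeline front end: one call running raw detection -> sensing correction
# -> barycenter annotation, plus a thin command-line interface (see
# inst/cli/afdetect.R).

#' Run the full detection pipeline on one record
#'
#' Executes the stages in order: raw detection (relative-energy or
#' adaptive-morphology), over/undersensing correction, barycenter annotation
#' correction. Every stage's output is returned; when \code{truth} is given,
#' error rates are computed for each stage.
#'
#' @param rec an \code{iegm_record}.
#' @param algo \code{"relen"} or \code{"amm"}.
#' @param params detector parameters (algorithm defaults when \code{NULL}).
#' @param wp \code{weight_params} for the sensing correction (per-detector
#'   defaults when \code{NULL}).
#' @param bp \code{barycenter_params} for the annotation correction.
#' @param truth optional reference \code{activation_sequence}.
#' @param tol matching tolerance for evaluation, ms.
#' @return object of class \code{afdetect_result}: list with \code{raw},
#'   \code{corrected}, \code{barycenter} (activation sequences),
#'   \code{variance} (\code{variance_report}), and, when truth is supplied,
#'   \code{rates} (list of \code{error_rates} per stage).
#' @export
run_pipeline <- function(rec, algo = c("relen", "amm"), params = NULL,
                         wp = NULL, bp = barycenter_params(), truth = NULL,
                         tol = 35) {
  algo <- match.arg(algo)
  if (is.null(params)) params <- if (algo == "relen") relen_params() else amm_params()
  if (algo == "relen") {
    det <- relen_detect(rec, params)
    raw <- det$seq
    corrected <- if (length(raw$lats) >= 3L)
      correct_sequence(raw, wp, "relen", es = det$enhanced)
    else activation_sequence(raw$lats, raw$record_id, "corrected")
  } else {
    raw <- amm_detect(rec, params)
    corrected <- if (length(raw$lats) >= 3L)
      correct_sequence(raw, wp, "amm", rec = rec, params = params)
    else activation_sequence(raw$lats, raw$record_id, "corrected")
  }
  ann <- correct_annotations(rec, corrected, bp)
  out <- list(raw = raw, corrected = corrected, barycenter = ann$seq,
              variance = ann$report, algo = algo)
  if (!is.null(truth)) {
    out$rates <- list(raw = error_rates(match_detections(raw, truth, tol)),
                      corrected = error_rates(match_detections(corrected, truth, tol)),
                      barycenter = error_rates(match_detections(ann$seq, truth, tol)))
  }
  class(out) <- "afdetect_result"
  out
}

#' @export
print.afdetect_result <- function(x, ...) {
  cat(sprintf("<afdetect_result> algo = %s\n", x$algo))
  cat(sprintf("  raw: %d, corrected: %d, barycenter-annotated: %d activations\n",
              length(x$raw$lats), length(x$corrected$lats), length(x$barycenter$lats)))
  cat(sprintf("  interval variance change: %+.1f%%\n", 100 * x$variance$relative_change))
  if (!is.null(x$rates))
    for (st in names(x$rates))
      cat(sprintf("  %-10s FN %.2f%%  FP %.2f%%  total %.2f%%\n", st,
                  x$rates[[st]]$fn_rate, x$rates[[st]]$fp_rate, x$rates[[st]]$total))
  invisible(x)
}

# --- minimal command-line front end ------------------------------------------

cli_opts <- function(args) {
  opts <- list()
  pos <- character(0)
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (grepl("^-", a)) {
      key <- sub("^-+", "", a)
      if (i < length(args) && !grepl("^-[^0-9.]", args[i + 1L])) {
        opts[[key]] <- args[i + 1L]; i <- i + 2L
      } else { opts[[key]] <- TRUE; i <- i + 1L }
    } else { pos <- c(pos, a); i <- i + 1L }
  }
  list(opts = opts, pos = pos)
}

cli_num <- function(opts, key, default) if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
cli_chr <- function(opts, key, default) if (is.null(opts[[key]])) default else as.character(opts[[key]])

#' Command-line entry point
#'
#' Subcommands: \code{simulate} (write a synthetic corpus), \code{detect}
#' (raw detection to an annotation file), \code{run} (full pipeline),
#' \code{evaluate} (error rates of an annotation file against a truth file).
#' Used by the \code{inst/cli/afdetect.R} wrapper script; see the README for
#' the option list.
#'
#' @param args character vector of command-line arguments (defaults to
#'   \code{commandArgs(trailingOnly = TRUE)}).
#' @return integer exit status (0 ok, 1 usage error, 2 runtime error).
#' @export
afdetect_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: afdetect <command> [options]",
    "  simulate --n N --seed S --duration SEC --out DIR [--noise SD] [--mean-cl MS]",
    "  detect   --algo relen|amm -i REC.csv -o ANN.json [--swin MS --lwin MS --percentile P]",
    "  run      --algo relen|amm -i REC.csv -o PREFIX [--truth TRUTH.json]",
    "  evaluate -a ANN.json -t TRUTH.json [--tol MS]",
    sep = "\n")
  if (!length(args)) { message(usage); return(1L) }
  cmd <- args[1L]
  parsed <- cli_opts(args[-1L])
  o <- parsed$opts
  status <- tryCatch({
    if (cmd == "simulate") {
      dir <- cli_chr(o, "out", "corpus")
      if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
      cfg <- synth_config(duration = cli_num(o, "duration", 10),
                          mean_cl = cli_num(o, "mean-cl", 220),
                          noise_sd = cli_num(o, "noise", 0.03))
      make_corpus(cfg, n_records = cli_num(o, "n", 1), seed = cli_num(o, "seed", 1),
                  dir = dir)
      0L
    } else if (cmd == "detect") {
      rec <- read_record(cli_chr(o, "i", stop("detect requires -i", call. = FALSE)))
      algo <- cli_chr(o, "algo", "relen")
      s <- if (algo == "relen") {
        p <- relen_params(s_win = cli_num(o, "swin", 100),
                          l_win = cli_num(o, "lwin", 400),
                          percentile = cli_num(o, "percentile", 11),
                          p_exp = cli_num(o, "pexp", 4),
                          refractory = cli_num(o, "refractory", 70))
        relen_detect(rec, p)$seq
      } else {
        p <- amm_params(se_duration = cli_num(o, "se-duration", 20),
                        alpha = cli_num(o, "alpha", 0.5),
                        refractory = cli_num(o, "refractory", 70))
        amm_detect(rec, p)
      }
      write_annotations(s, cli_chr(o, "o", "annotations.json"))
      0L
    } else if (cmd == "run") {
      rec <- read_record(cli_chr(o, "i", stop("run requires -i", call. = FALSE)))
      truth <- if (!is.null(o[["truth"]])) read_annotations(o[["truth"]]) else NULL
      res <- run_pipeline(rec, algo = cli_chr(o, "algo", "relen"), truth = truth)
      prefix <- cli_chr(o, "o", "afdetect_out")
      write_annotations(res$raw, paste0(prefix, "_raw.json"))
      write_annotations(res$corrected, paste0(prefix, "_corrected.json"))
      write_annotations(res$barycenter, paste0(prefix, "_barycenter.json"))
      print(res)
      0L
    } else if (cmd == "evaluate") {
      det <- read_annotations(cli_chr(o, "a", stop("evaluate requires -a", call. = FALSE)))
      truth <- read_annotations(cli_chr(o, "t", stop("evaluate requires -t", call. = FALSE)))
      print(error_rates(match_detections(det, truth, cli_num(o, "tol", 35))))
      0L
    } else { message(usage); 1L }
  }, error = function(e) { message("afdetect: ", conditionMessage(e)); 2L })
  status
}
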