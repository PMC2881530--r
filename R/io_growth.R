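# Growth-series CSV serialization.
# Schema: time_h, od, acetate_mM, o2_cum_umol, volume_ml; rows time-sorted.

#' Read a growth experiment from CSV
#'
#' @param path CSV with header `time_h, od, acetate_mM, o2_cum_umol,
#'   volume_ml`.
#' @return A [growth_experiment()]. Non-monotone time or O2 columns raise
#'   format errors.
#' @export
read_growth_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("time_h", "od", "acetate_mM", "o2_cum_umol", "volume_ml")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop(sprintf("growth series '%s' lacks column(s): %s", path,
                 paste(miss, collapse = ", ")))
  }
  growth_experiment(df$time_h, df$od, df$acetate_mM, df$o2_cum_umol,
                    df$volume_ml)
}

#' Write a growth experiment to CSV
#'
#' Inverse of [read_growth_series()].
#' @param experiment A [growth_experiment()].
#' @param path Destination CSV.
#' @return `path`, invisibly.
#' @export
write_growth_series <- function(experiment, path) {
  stopifnot(inherits(experiment, "growth_experiment"))
  df <- data.frame(time_h = experiment$time_h, od = experiment$od,
                   acetate_mM = experiment$acetate_mM,
                   o2_cum_umol = experiment$o2_cum_umol,
                   volume_ml = experiment$volume_ml)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
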