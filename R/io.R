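# Delimited-text I/O. All tables are tab-separated with a one-line header.

#' Write a table as tab-delimited text
#'
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_delim_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a tab-delimited table
#'
#' @param path input path.
#' @return data frame.
#' @export
read_delim_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write spike-time and epoch tables for a cohort
#'
#' Spike table columns: `unit_id`, `t_spike_s`. Epoch table columns:
#' `unit_id`, `label`, `start_s`, `end_s`. A third unit-metadata table
#' (`unit_id`, `organ`, `condition`, `seed`) preserves what the tables alone
#' cannot carry.
#'
#' @param trains list of `spike_train`.
#' @param dir output directory (created if missing).
#' @return named character vector of the three file paths, invisibly.
#' @export
write_spike_tables <- function(trains, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  spikes <- do.call(rbind, lapply(trains, function(tr) {
    data.frame(unit_id = tr$unit_id, t_spike_s = tr$spike_times,
               stringsAsFactors = FALSE)
  }))
  epochs <- do.call(rbind, lapply(trains, function(tr) {
    data.frame(unit_id = tr$unit_id, label = tr$epochs$label,
               start_s = tr$epochs$start, end_s = tr$epochs$end,
               stringsAsFactors = FALSE)
  }))
  units <- do.call(rbind, lapply(trains, function(tr) {
    data.frame(unit_id = tr$unit_id, organ = tr$organ,
               condition = tr$condition, seed = tr$seed,
               stringsAsFactors = FALSE)
  }))
  paths <- c(spikes = file.path(dir, "spike_times.tsv"),
             epochs = file.path(dir, "epochs.tsv"),
             units = file.path(dir, "units.tsv"))
  write_delim_table(spikes, paths["spikes"])
  write_delim_table(epochs, paths["epochs"])
  write_delim_table(units, paths["units"])
  invisible(paths)
}

#' Read spike-time and epoch tables back into spike trains
#'
#' @param dir directory containing `spike_times.tsv`, `epochs.tsv`,
#'   `units.tsv` as written by [write_spike_tables()].
#' @return list of `spike_train`.
#' @export
read_spike_tables <- function(dir) {
  spikes <- read_delim_table(file.path(dir, "spike_times.tsv"))
  epochs <- read_delim_table(file.path(dir, "epochs.tsv"))
  units <- read_delim_table(file.path(dir, "units.tsv"))
  lapply(seq_len(nrow(units)), function(i) {
    uid <- units$unit_id[i]
    ep <- epochs[epochs$unit_id == uid, , drop = FALSE]
    as_spike_train(
      unit_id = uid,
      spike_times = sort(spikes$t_spike_s[spikes$unit_id == uid]),
      epochs = data.frame(label = ep$label, start = ep$start_s, end = ep$end_s,
                          stringsAsFactors = FALSE),
      organ = units$organ[i], condition = units$condition[i])
  })
}
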