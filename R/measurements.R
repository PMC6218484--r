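#' Construct a multi-context experiment table
#'
#' Holds the quantitative data a network is contextualized against: for each
#' cellular context (cell line) and experimental condition, the mean
#' normalized activity of every measured node, its standard error and the
#' replicate count, plus the input clamps defining each condition.
#' All means live on the min-max normalized \[0,1\] scale.
#'
#' @param measurements data.frame with columns `context`, `condition`,
#'   `node`, `mean` (in \[0,1\]), `sem` (>= 0) and `n` (replicates).
#' @param conditions data.frame of input clamps with columns `condition`,
#'   `node`, `value` (in \[0,1\]); every condition referenced in
#'   `measurements` must be defined here.
#' @param network optional [logic_network()] to validate node names and roles
#'   against (clamped nodes must be `input` or `constitutive`; measured nodes
#'   must exist).
#' @param time_label optional tag such as `"16h"`.
#' @return An object of class `experiment_table`. The number of fitted data
#'   points `N` equals `nrow(measurements)`.
#' @export
experiment_table <- function(measurements, conditions, network = NULL,
                             time_label = NULL) {
  measurements <- as.data.frame(measurements, stringsAsFactors = FALSE)
  conditions <- as.data.frame(conditions, stringsAsFactors = FALSE)
  need_m <- c("context", "condition", "node", "mean", "sem", "n")
  if (!all(need_m %in% names(measurements)))
    stop("schema error: measurements need columns ",
         paste(need_m, collapse = ", "))
  if (!all(c("condition", "node", "value") %in% names(conditions)))
    stop("schema error: conditions need columns condition, node, value")
  if (!nrow(conditions)) stop("no input clamps defined")
  if (!nrow(measurements)) stop("validation error: empty measurement table")
  if (any(!is.finite(measurements$mean)) ||
      any(measurements$mean < 0 | measurements$mean > 1))
    stop("validation error: measurement means must lie in [0,1]")
  if (any(measurements$sem < 0))
    stop("validation error: SEM must be non-negative")
  if (any(conditions$value < 0 | conditions$value > 1))
    stop("validation error: input clamps must lie in [0,1]")
  undef <- setdiff(unique(measurements$condition), unique(conditions$condition))
  if (length(undef))
    stop("schema error: condition(s) without input clamps: ",
         paste(undef, collapse = ", "))
  if (!is.null(network)) {
    stopifnot(inherits(network, "logic_network"))
    unk <- setdiff(unique(c(measurements$node, conditions$node)),
                   network$nodes$name)
    if (length(unk))
      stop("schema error: unknown node(s): ", paste(unk, collapse = ", "))
    clampable <- clamped_names(network)
    bad <- setdiff(unique(conditions$node), clampable)
    if (length(bad))
      stop("schema error: clamped node(s) not input/constitutive: ",
           paste(bad, collapse = ", "))
  }
  structure(list(measurements = measurements, conditions = conditions,
                 contexts = unique(measurements$context),
                 time_label = time_label),
            class = "experiment_table")
}

#' Read measurements and input clamps from delimited files
#'
#' Both files are tab-delimited with a header row. The measurement file is in
#' long format with columns `context`, `condition`, `node`, `mean`, `sem`,
#' `n`; the condition sheet has columns `condition`, `node`, `value` and
#' defines the input clamps of every condition.
#'
#' @param meas_file path to the measurement table.
#' @param cond_file path to the condition (input-clamp) sheet.
#' @inheritParams experiment_table
#' @return An [experiment_table()].
#' @export
read_measurements <- function(meas_file, cond_file, network = NULL,
                              time_label = NULL) {
  meas <- utils::read.delim(meas_file, stringsAsFactors = FALSE)
  cond <- utils::read.delim(cond_file, stringsAsFactors = FALSE)
  if (!nrow(cond)) stop("no input clamps defined")
  experiment_table(meas, cond, network = network, time_label = time_label)
}

#' Write an experiment table to delimited files
#'
#' @param table an [experiment_table()].
#' @param meas_file,cond_file output paths.
#' @return `table`, invisibly.
#' @export
write_measurements <- function(table, meas_file, cond_file) {
  stopifnot(inherits(table, "experiment_table"))
  utils::write.table(table$measurements, meas_file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(table$conditions, cond_file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(table)
}

#' @export
print.experiment_table <- function(x, ...) {
  m <- x$measurements
  cat(sprintf("Experiment table: N = %d data points%s\n", nrow(m),
              if (!is.null(x$time_label)) paste0(" [", x$time_label, "]") else ""))
  cat(sprintf("  contexts: %s\n", paste(x$contexts, collapse = ", ")))
  cat(sprintf("  conditions: %d, measured nodes: %d\n",
              length(unique(m$condition)), length(unique(m$node))))
  invisible(x)
}

#' Number of fitted data points in an experiment table
#'
#' @param table an [experiment_table()].
#' @return Integer `N`, the number of (context, condition, node) rows.
#' @export
n_datapoints <- function(table) {
  stopifnot(inherits(table, "experiment_table"))
  nrow(table$measurements)
}

# internal: clamp list (named numeric vector) for one condition
condition_clamps <- function(table, condition) {
  cc <- table$conditions[table$conditions$condition == condition, , drop = FALSE]
  stats::setNames(cc$value, cc$node)
}

# internal: subset an experiment table to selected contexts
subset_contexts <- function(table, contexts) {
  m <- table$measurements[table$measurements$context %in% contexts, , drop = FALSE]
  experiment_table(m, table$conditions, time_label = table$time_label)
}
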