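#' Write / read a windowed dataset as per-sample CSV files
#'
#' Text layout: one CSV per window named `sample_<i>.csv` (rows = timesteps,
#' columns = channels, header `ch1..chC`), plus a sidecar `samples.csv` with
#' columns `file`, `label`, `split`, and, when the dataset is normalised, a
#' `channel_stats.csv` with columns `mean`, `sd`.
#'
#' @param ds a [WindowedDataset-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
writeDatasetCSV <- function(ds, dir) {
  stopifnot(is(ds, "WindowedDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(ds@signals)
  files <- sprintf("sample_%04d.csv", seq_len(d[1L]))
  for (i in seq_len(d[1L])) {
    m <- ds@signals[i, , ]
    colnames(m) <- paste0("ch", seq_len(d[3L]))
    utils::write.csv(m, file.path(dir, files[i]), row.names = FALSE)
  }
  utils::write.csv(
    data.frame(file = files, label = ds@labels, split = ds@split),
    file.path(dir, "samples.csv"),
    row.names = FALSE
  )
  if (nrow(ds@channelStats)) {
    utils::write.csv(ds@channelStats, file.path(dir, "channel_stats.csv"),
      row.names = FALSE)
  }
  invisible(dir)
}

#' @rdname writeDatasetCSV
#' @param nClasses integer; inferred as `max(label) + 1` when NULL.
#' @export
readDatasetCSV <- function(dir, nClasses = NULL) {
  sidecar <- utils::read.csv(file.path(dir, "samples.csv"),
    stringsAsFactors = FALSE)
  first <- as.matrix(utils::read.csv(file.path(dir, sidecar$file[1L])))
  sig <- array(0, c(nrow(sidecar), nrow(first), ncol(first)))
  sig[1L, , ] <- first
  for (i in seq_len(nrow(sidecar))[-1L]) {
    sig[i, , ] <- as.matrix(utils::read.csv(file.path(dir, sidecar$file[i])))
  }
  statsFile <- file.path(dir, "channel_stats.csv")
  cs <- if (file.exists(statsFile)) utils::read.csv(statsFile) else data.frame()
  methods::new("WindowedDataset",
    signals = sig,
    labels = as.integer(sidecar$label),
    split = as.character(sidecar$split),
    nClasses = as.integer(nClasses %||% (max(sidecar$label) + 1L)),
    channelStats = cs
  )
}

#' Single-file tensor archive for a dataset (plus optional corruption record)
#'
#' A binary one-file interchange format (R serialisation) holding the signal
#' tensor, labels, split tags, channel statistics and, when given, the
#' corruption record. Intended for run-time hand-off between pipeline stages.
#'
#' @param ds a [WindowedDataset-class].
#' @param path output file path.
#' @param record optional [CorruptionRecord-class].
#' @return invisibly, the path.
#' @export
writeDatasetArchive <- function(ds, path, record = NULL) {
  stopifnot(is(ds, "WindowedDataset"))
  saveRDS(list(
    signals = ds@signals, labels = ds@labels, split = ds@split,
    nClasses = ds@nClasses, channelStats = ds@channelStats,
    corruption = if (is.null(record)) NULL else list(
      indices = record@indices, originalLabels = record@originalLabels,
      rate = record@rate, seed = record@seed
    )
  ), path)
  invisible(path)
}

#' @rdname writeDatasetArchive
#' @export
readDatasetArchive <- function(path) {
  x <- readRDS(path)
  ds <- methods::new("WindowedDataset",
    signals = x$signals, labels = x$labels, split = x$split,
    nClasses = x$nClasses, channelStats = x$channelStats
  )
  record <- NULL
  if (!is.null(x$corruption)) {
    record <- methods::new("CorruptionRecord",
      indices = x$corruption$indices,
      originalLabels = x$corruption$originalLabels,
      rate = x$corruption$rate, seed = x$corruption$seed
    )
  }
  list(dataset = ds, record = record)
}

#' Write / read a value table as CSV
#'
#' Columns: `index` (dataset index of the training window), `value`
#' (selection probability, full double precision) and, when a corruption
#' record is supplied, `is_corrupted` (0/1).
#'
#' @param valueTable a [ValueTable-class].
#' @param path output CSV path.
#' @param record optional [CorruptionRecord-class].
#' @return invisibly, the path.
#' @export
writeValueTable <- function(valueTable, path, record = NULL) {
  stopifnot(is(valueTable, "ValueTable"))
  df <- data.frame(
    index = valueTable@sampleIndex,
    value = sprintf("%.15g", valueTable@probs)
  )
  if (!is.null(record)) {
    df$is_corrupted <- as.integer(valueTable@sampleIndex %in% record@indices)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeValueTable
#' @export
readValueTable <- function(path) {
  df <- utils::read.csv(path)
  methods::new("ValueTable",
    probs = as.numeric(df$value),
    sampleIndex = as.integer(df$index)
  )
}

#' Write an evaluation curve as CSV
#'
#' CSD curves get columns `fraction`, `discovery`, `optimal`; RHLVS curves
#' get `fraction`, `remove_high_acc`, `remove_low_acc`.
#'
#' @param curve a [CSDCurve-class] or [RHLVSCurve-class].
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writeCurveCSV <- function(curve, path) {
  df <- if (is(curve, "CSDCurve")) {
    data.frame(
      fraction = curve@removalFractions,
      discovery = curve@discovery,
      optimal = curve@optimal
    )
  } else if (is(curve, "RHLVSCurve")) {
    data.frame(
      fraction = curve@removalFractions,
      remove_high_acc = curve@removeHighAcc,
      remove_low_acc = curve@removeLowAcc
    )
  } else {
    stop("curve must be a CSDCurve or RHLVSCurve")
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' End-to-end run configuration
#'
#' Bundles the nested stage configurations with the corruption rate, output
#' directory and master seed (which propagates to every stochastic stage).
#' Can also be populated from a YAML file via [readRunConfig()].
#'
#' @param spec a [syntheticSpec()] describing the dataset.
#' @param trainer a [trainerConfig()].
#' @param dve a [dveConfig()].
#' @param predictor a [predictorConfig()].
#' @param classifier a [classifierSpec()].
#' @param corruptionRate numeric in `[0, 1]`.
#' @param rhlvsIterations,rhlvsBatch classifier training budget per
#'   RHLVS retraining.
#' @param outDir output directory.
#' @param seed integer master seed (overrides the nested seeds).
#' @return a list of class `"runConfig"`.
#' @export
runConfig <- function(spec = syntheticSpec(), trainer = trainerConfig(),
                      dve = dveConfig(), predictor = predictorConfig(),
                      classifier = classifierSpec("public_baseline"),
                      corruptionRate = 0.2, rhlvsIterations = 60L,
                      rhlvsBatch = 32L, outDir = tempfile("harvalue_run"),
                      seed = 1L) {
  if (!is.finite(corruptionRate) || corruptionRate < 0 || corruptionRate > 1) {
    stop("corruptionRate must be in [0,1]")
  }
  structure(
    list(
      spec = spec, trainer = trainer, dve = dve, predictor = predictor,
      classifier = classifier, corruptionRate = corruptionRate,
      rhlvsIterations = as.integer(rhlvsIterations),
      rhlvsBatch = as.integer(rhlvsBatch),
      outDir = outDir, seed = as.integer(seed)
    ),
    class = "runConfig"
  )
}

#' Read a run configuration from a YAML file
#'
#' Recognised top-level keys mirror the [runConfig()] arguments; nested
#' mappings `spec`, `trainer`, `dve`, `predictor` take the corresponding
#' constructor arguments, `classifier` is a variant name.
#'
#' @param path YAML file path.
#' @return a `"runConfig"`.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$spec)) args$spec <- do.call(syntheticSpec, y$spec)
  if (!is.null(y$trainer)) args$trainer <- do.call(trainerConfig, y$trainer)
  if (!is.null(y$dve)) args$dve <- do.call(dveConfig, y$dve)
  if (!is.null(y$predictor)) args$predictor <- do.call(predictorConfig, y$predictor)
  if (!is.null(y$classifier)) args$classifier <- classifierSpec(y$classifier)
  for (k in c("corruptionRate", "rhlvsIterations", "rhlvsBatch", "outDir",
              "seed")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  do.call(runConfig, args)
}

#' Run the full valuation pipeline end to end
#'
#' Generate -> normalise -> corrupt -> pretrain `f_v` -> train valuation ->
#' CSD -> RHLVS. Writes the value table, both curve CSVs and a JSON report of
#' summary statistics to `cfg$outDir`, and returns the report (with the
#' intermediate objects attached as attributes). With `corruptionRate = 0`
#' the CSD stage is skipped and the report notes it.
#'
#' @param cfg a [runConfig()].
#' @param verbose logical, forwarded to [trainValuation()].
#' @return the report: a list with entries `maximum_discovery`,
#'   `removed_data_at_max_discovery`, `maximum_accuracy`,
#'   `improved_accuracy`, `removed_data_at_max_accuracy` (percent scale),
#'   plus `notes`.
#' @export
runDemo <- function(cfg = runConfig(), verbose = FALSE) {
  stopifnot(inherits(cfg, "runConfig"))
  dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
  spec <- cfg$spec
  spec$seed <- cfg$seed
  ds <- normalizeDataset(generateDataset(spec))
  record <- NULL
  if (cfg$corruptionRate > 0) {
    cor <- corruptLabels(ds, cfg$corruptionRate, seed = childSeed(cfg$seed, 2L))
    ds <- cor$dataset
    record <- cor$record
  }
  trainer <- cfg$trainer
  trainer$seed <- childSeed(cfg$seed, 3L)
  vt <- trainValuation(ds, trainer, cfg$dve, cfg$predictor, verbose = verbose)
  writeValueTable(vt, file.path(cfg$outDir, "value_table.csv"), record)

  report <- list(notes = character())
  if (!is.null(record) && length(record@indices)) {
    cs <- csd(vt, record)
    writeCurveCSV(cs, file.path(cfg$outDir, "csd_curve.csv"))
    best <- which.max(cs@discovery)
    report$maximum_discovery <- 100 * max(cs@discovery)
    report$removed_data_at_max_discovery <- 100 * cs@removalFractions[best]
  } else {
    report$maximum_discovery <- NA_real_
    report$removed_data_at_max_discovery <- NA_real_
    report$notes <- c(report$notes,
      "corruption rate 0: CSD stage skipped (no corrupted samples)")
    cs <- NULL
  }
  rh <- rhlvs(ds, vt, cfg$classifier, seed = childSeed(cfg$seed, 4L),
    iterations = cfg$rhlvsIterations, batch = cfg$rhlvsBatch)
  writeCurveCSV(rh, file.path(cfg$outDir, "rhlvs_curve.csv"))
  bestAcc <- which.max(rh@removeLowAcc)
  report$maximum_accuracy <- 100 * max(rh@removeLowAcc)
  report$improved_accuracy <- 100 * (max(rh@removeLowAcc) - rh@removeLowAcc[1L])
  report$removed_data_at_max_accuracy <- 100 * rh@removalFractions[bestAcc]

  jsonlite::write_json(
    report[c("maximum_discovery", "removed_data_at_max_discovery",
             "maximum_accuracy", "improved_accuracy",
             "removed_data_at_max_accuracy", "notes")],
    file.path(cfg$outDir, "report.json"),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null"
  )
  attr(report, "valueTable") <- vt
  attr(report, "csd") <- cs
  attr(report, "rhlvs") <- rh
  attr(report, "record") <- record
  report
}
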