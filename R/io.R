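.quantColumns <- c("protein", "peptide", "charge", "time", "experiment",
                   paste0("A", 0:5))

#' Read a peptide quantification table
#'
#' Reads the per-peptide isotopomer abundance CSV (the same schema the
#' simulator emits): protein, peptide, charge, time, experiment,
#' A0..A5. Comment lines starting with `#` (provenance headers) are
#' skipped. Rows with negative abundances or duplicated
#' (peptide, charge, time, experiment) keys are dropped with a warning.
#'
#' @param path CSV path.
#' @return Data frame in the documented column order.
#' @export
readQuantCsv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  missing <- setdiff(.quantColumns, names(tab))
  if (length(missing))
    stop("quantification table is missing required column(s): ",
         paste(missing, collapse = ", "))
  tab <- tab[, .quantColumns]
  if (nrow(tab)) {
    neg <- rowSums(tab[, paste0("A", 0:5)] < 0, na.rm = TRUE) > 0
    if (any(neg)) {
      warning(sum(neg), " row(s) with negative abundances skipped")
      tab <- tab[!neg, ]
    }
    key <- do.call(paste, c(tab[, c("peptide", "charge", "time",
                                    "experiment")], sep = "\r"))
    dup <- duplicated(key)
    if (any(dup)) {
      warning(sum(dup), " duplicated row(s) skipped")
      tab <- tab[!dup, ]
    }
  }
  rownames(tab) <- NULL
  tab
}

.writeCsvWithHeader <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", provenance), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Write a quantification table
#'
#' @param quant Data frame in the [readQuantCsv()] schema.
#' @param path Output CSV path.
#' @param provenance Optional character vector echoed as `#` header
#'   lines.
#' @export
writeQuantCsv <- function(quant, path, provenance = NULL) {
  stopifnot(all(.quantColumns %in% names(quant)))
  .writeCsvWithHeader(quant[, .quantColumns], path, provenance)
}

#' Write a rate-constant table
#'
#' Writes per-peptide or per-protein turnover results (any data frame,
#' typically from [turnoverFitTable()] or [aggregateProteins()]) with an
#' optional provenance header.
#'
#' @param rates Data frame of results.
#' @param path Output CSV path.
#' @param provenance Optional character vector echoed as `#` headers.
#' @export
writeRatesCsv <- function(rates, path, provenance = NULL) {
  .writeCsvWithHeader(rates, path, provenance)
}

#' Read an analysis configuration file
#'
#' YAML (or plain `key: value`) configuration with any of: p_w, p_h,
#' time_points, neh_table (path), min_timepoints, r2_threshold,
#' rse_slow, ratios. Unknown keys are kept and passed through.
#'
#' @param path Config file path.
#' @return Named list of parameters.
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config file must parse to key-value pairs")
  cfg
}

#' Read a deposited per-protein quantification CSV
#'
#' Tolerant adapter for externally deposited per-protein quantification
#' tables, which name columns in several dialects. Maps recognized
#' variants onto the package schema and returns a [readQuantCsv()]-style
#' data frame. Isolated from the core modules: nothing else depends on
#' it.
#'
#' @param path CSV path.
#' @param protein Protein identifier to assign (defaults to the file
#'   name without extension).
#' @return Data frame in the package quantification schema.
#' @export
readDepositedProteinCsv <- function(path, protein = NULL) {
  if (is.null(protein))
    protein <- sub("\\.[Cc][Ss][Vv]$", "", basename(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  nm <- tolower(gsub("[^a-z0-9]", "", tolower(names(raw))))
  pick <- function(cands) {
    hit <- which(nm %in% cands)
    if (length(hit)) raw[[hit[1]]] else NULL
  }
  out <- data.frame(
    protein = protein,
    peptide = pick(c("peptide", "peptideseq", "sequence", "peptidesequence")),
    charge = pick(c("charge", "z", "chargestate")),
    time = pick(c("time", "timedays", "labelingtime", "day", "days",
                  "experimenttime")),
    experiment = {
      e <- pick(c("experiment", "experimentid", "file", "rawfile", "run"))
      if (is.null(e)) "deposited" else e
    },
    stringsAsFactors = FALSE)
  for (i in 0:5) {
    col <- pick(c(paste0("a", i), paste0("i", i), paste0("m", i),
                  paste0("isotope", i), paste0("abundance", i)))
    if (is.null(col))
      stop("could not locate abundance column for isotopomer ", i)
    out[[paste0("A", i)]] <- as.numeric(col)
  }
  if (is.null(out$peptide) || is.null(out$charge) || is.null(out$time))
    stop("could not map peptide/charge/time columns in ", path)
  out
}

#' Run the full turnover pipeline on a quantification table
#'
#' For every peptide/charge time course: builds the four candidate
#' monoisotopic-RIA series, fits the exponential decay to each, selects
#' the best method, applies the acceptance filters, scores spectral
#' accuracy per time point, and aggregates accepted peptides to protein
#' rates.
#'
#' @param quant Quantification data frame ([readQuantCsv()] schema).
#' @param params A [LabelingParameters-class].
#' @param nehTable Per-residue exchangeable-hydrogen table.
#' @param minTimepoints,r2Threshold,kRange,rseSlow Passed to
#'   [applyFilters()].
#' @param methods RIA-construction methods to evaluate.
#' @param bestOnly If TRUE (default) only the selected best fit per
#'   peptide enters the peptide table; otherwise all per-method fits are
#'   returned with the selected one marked.
#' @return List with data frames `peptides` (fits + filter columns),
#'   `proteins` (rollup), and `qc` (spectral accuracy per time point).
#' @export
runTurnoverPipeline <- function(quant, params = labelingParameters(),
                                nehTable = defaultNehTable(),
                                minTimepoints = 4L, r2Threshold = 0.8,
                                kRange = NULL, rseSlow = 0.05,
                                methods = .riaMethods, bestOnly = TRUE) {
  stopifnot(all(.quantColumns %in% names(quant)))
  groups <- split(quant, list(quant$protein, quant$peptide, quant$charge),
                  drop = TRUE)
  pepRows <- list(); qcRows <- list()
  for (g in groups) {
    comp <- tryCatch(peptideComposition(g$peptide[1], g$charge[1], nehTable),
                     error = function(e) {
                       warning("skipping peptide ", g$peptide[1], ": ",
                               conditionMessage(e))
                       NULL
                     })
    if (is.null(comp)) next
    nat <- naturalIsotopeDistribution(comp)
    res <- fitAllMethods(g[order(g$time), ], comp, params,
                         methods = methods, natural = nat)
    take <- if (bestOnly) list(res$best) else res$fits
    tab <- turnoverFitTable(take, peptide = g$peptide[1],
                            protein = g$protein[1], charge = g$charge[1])
    tab$selected <- tab$method == res$best@method
    pepRows[[length(pepRows) + 1L]] <- tab

    sLab <- labeledIsotopomerRias(nat, params@pW, comp@nExchangeable,
                                  params@pH)
    u <- .isoNum(nat) / sum(.isoNum(nat))
    l <- .isoNum(sLab) / sum(.isoNum(sLab))
    for (i in seq_len(nrow(g))) {
      a <- as.numeric(g[i, paste0("A", 0:5)])
      if (sum(a) <= 0) next
      cf <- fitTheta(a / sum(a), u, l)
      qcRows[[length(qcRows) + 1L]] <- data.frame(
        protein = g$protein[1], peptide = g$peptide[1],
        charge = g$charge[1], time = g$time[i],
        theta = cf@theta, ssd = cf@ssd,
        ln_ssd = log(max(cf@ssd, 1e-12)), stringsAsFactors = FALSE)
    }
  }
  peptides <- do.call(rbind, c(pepRows, list(make.row.names = FALSE)))
  if (is.null(peptides))
    stop("no peptide could be processed from the quantification table")
  peptides <- applyFilters(peptides, minTimepoints, r2Threshold,
                           kRange, rseSlow)
  rollupIn <- peptides[peptides$selected, ]
  proteins <- aggregateProteins(rollupIn)
  qc <- do.call(rbind, c(qcRows, list(make.row.names = FALSE)))
  list(peptides = peptides, proteins = proteins, qc = qc)
}
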