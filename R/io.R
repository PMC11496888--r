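#' Read per-locus summary statistics from text files
#'
#' The z file is whitespace-delimited: either a single headerless numeric
#' column of z-scores, or a table whose header contains at least `rsid` and
#' `z` columns. The LD file is an m x m whitespace-delimited numeric matrix.
#' Small LD asymmetries (up to 1e-3) are symmetrized as `(A + t(A)) / 2`
#' with a warning when the asymmetry exceeds 1e-6. Extreme z-scores (e.g.
#' infinities printed by some GWAS pipelines) can be clipped in magnitude
#' with `z_clip`.
#'
#' @param z_path Path to the z-score file.
#' @param ld_path Path to the LD matrix file.
#' @param n_samples GWAS sample size.
#' @param z_clip Optional positive clip on |z|.
#' @return A [summary_input()] object.
#' @export
read_summary <- function(z_path, ld_path, n_samples, z_clip = NULL) {
  if (!file.exists(z_path)) stop(sprintf("z file not found: %s", z_path))
  if (!file.exists(ld_path)) stop(sprintf("LD file not found: %s", ld_path))
  first <- readLines(z_path, n = 1L)
  toks <- strsplit(trimws(first), "\\s+")[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(toks))))
  if (has_header) {
    tab <- utils::read.table(z_path, header = TRUE, stringsAsFactors = FALSE)
    names(tab) <- tolower(names(tab))
    if (!"z" %in% names(tab)) stop("z file header must contain a `z` column")
    z <- as.numeric(tab$z)
    ids <- if ("rsid" %in% names(tab)) as.character(tab$rsid) else NULL
  } else {
    tab <- utils::read.table(z_path, header = FALSE)
    z <- as.numeric(tab[[ncol(tab)]])
    ids <- NULL
  }
  if (anyNA(z)) {
    stop(sprintf("non-numeric z value near line %d of %s",
                 which(is.na(z))[1] + has_header, z_path))
  }
  if (!is.null(z_clip)) {
    if (z_clip <= 0) stop("`z_clip` must be positive")
    z <- pmin(pmax(z, -z_clip), z_clip)
  }
  ld <- as.matrix(utils::read.table(ld_path, header = FALSE))
  dimnames(ld) <- NULL
  if (!is.numeric(ld) || anyNA(ld)) stop(sprintf("non-numeric cell in %s", ld_path))
  if (nrow(ld) != length(z)) {
    stop(sprintf("dimension mismatch: %d z-scores but LD is %d x %d",
                 length(z), nrow(ld), ncol(ld)))
  }
  asym <- max(abs(ld - t(ld)))
  if (asym > 1e-6) {
    warning(sprintf("LD asymmetry %.3g; symmetrizing as (A + t(A))/2", asym))
  }
  ld <- (ld + t(ld)) / 2
  summary_input(z = z, ld = ld, n_samples = n_samples, variant_ids = ids)
}

#' Write a simulated locus to text files
#'
#' Emits the same formats [read_summary()] consumes — `z.tsv` (rsid + z),
#' `ld.tsv` (m x m matrix) — plus `truth.tsv` (variant index, causal flag,
#' true effect size; 1-based indices).
#'
#' @param locus A [simulate_locus()] result.
#' @param outdir Output directory, created if needed.
#' @return Invisibly, the named vector of file paths.
#' @export
write_locus <- function(locus, outdir) {
  stopifnot(inherits(locus, "sim_locus"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  m <- locus$summary$m
  paths <- c(z = file.path(outdir, "z.tsv"),
             ld = file.path(outdir, "ld.tsv"),
             truth = file.path(outdir, "truth.tsv"))
  utils::write.table(
    data.frame(rsid = sprintf("var%04d", seq_len(m)),
               z = sprintf("%.17g", locus$summary$z)),
    paths[["z"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(matrix(sprintf("%.17g", locus$summary$ld), m, m),
                     paths[["ld"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  beta_full <- numeric(m)
  beta_full[locus$causal_indices] <- locus$beta
  utils::write.table(
    data.frame(variant = seq_len(m), causal = locus$truth, beta = beta_full),
    paths[["truth"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Write fine-mapping results to an output directory
#'
#' Emits `pip.tsv` (variant_id, pip), `credible_sets.json` (key variant,
#' coverage level, members; 1-based indices), `configs.tsv` (configuration
#' bitstring and normalized posterior), and `run_log.txt` (package version
#' plus the full resolved configuration). Variant identifiers default to
#' 1-based integer indices when the input carried none.
#'
#' @param result A [finemap_locus()] result.
#' @param outdir Output directory, created if needed.
#' @param config Optional named list echoed into the run log (seeds,
#'   hyperparameters).
#' @return Invisibly, the named vector of file paths.
#' @export
write_results <- function(result, outdir, config = NULL) {
  stopifnot(inherits(result, "finemap_result"))
  ok <- dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop(sprintf("cannot create output directory %s", outdir))
  m <- result$m
  ids <- if (is.null(result$variant_ids)) as.character(seq_len(m)) else result$variant_ids
  paths <- c(pip = file.path(outdir, "pip.tsv"),
             sets = file.path(outdir, "credible_sets.json"),
             configs = file.path(outdir, "configs.tsv"),
             log = file.path(outdir, "run_log.txt"))
  utils::write.table(
    data.frame(variant_id = ids, pip = sprintf("%.17g", result$pips)),
    paths[["pip"]], sep = "\t", quote = FALSE, row.names = FALSE)
  sets <- lapply(result$credible_sets, function(s) {
    list(key_variant = s$key_variant, rho = s$rho, members = s$members)
  })
  jsonlite::write_json(sets, paths[["sets"]], auto_unbox = TRUE, digits = NA)
  bitstring <- vapply(result$reduced$supports, function(sup) {
    b <- rep("0", m); b[sup] <- "1"; paste(b, collapse = "")
  }, character(1))
  utils::write.table(
    data.frame(config = bitstring, posterior = result$reduced$posterior),
    paths[["configs"]], sep = "\t", quote = FALSE, row.names = FALSE)
  lines <- c(sprintf("package: finecrete %s",
                     as.character(utils::packageVersion("finecrete"))),
             sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             sprintf("m: %d", m), sprintf("n_samples: %d", result$n_samples),
             sprintf("rho: %g", result$rho))
  if (!is.null(config)) {
    lines <- c(lines, vapply(names(config), function(k) {
      sprintf("%s: %s", k, paste(format(config[[k]]), collapse = " "))
    }, character(1)))
  }
  writeLines(lines, paths[["log"]])
  invisible(paths)
}
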