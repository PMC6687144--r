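# File formats and the pipeline driver. All curve/spectrum formats are
# plain CSV with `#` key=value metadata lines before the header; promoters
# are FASTA; hit tables are BED-like TSV; reports are JSON.

parse_meta_lines <- function(lines) {
  meta <- list()
  for (ln in lines) {
    body <- sub("^#\\s*", "", ln)
    kv <- strsplit(body, "=", fixed = TRUE)[[1L]]
    if (length(kv) == 2L) {
      val <- trimws(kv[2L])
      num <- suppressWarnings(as.numeric(val))
      meta[[trimws(kv[1L])]] <- if (!is.na(num)) num else val
    }
  }
  meta
}

read_headered_csv <- function(path, required_cols) {
  if (!file.exists(path))
    abort_uvf(sprintf("file not found: %s", path), "uvf_io_error")
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  is_meta <- grepl("^#", lines)
  meta <- parse_meta_lines(lines[is_meta])
  body <- lines[!is_meta]
  if (length(body) < 2L)
    abort_uvf(sprintf("%s: no data rows", path), "uvf_schema_error")
  df <- read.csv(text = paste(body, collapse = "\n"),
                 stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(df))
  extra <- setdiff(names(df), required_cols)
  if (length(missing) || length(extra))
    abort_uvf(sprintf("%s: schema mismatch (missing: %s; extra: %s)",
                      path,
                      paste(missing, collapse = ",") ,
                      paste(extra, collapse = ",")),
              "uvf_schema_error")
  list(data = df, meta = meta)
}

write_headered_csv <- function(df, meta, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    if (!is.null(meta[[k]]))
      writeLines(sprintf("# %s=%s", k, format(meta[[k]], digits = 17)), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a spectrum CSV
#'
#' Format: `#` metadata lines (`axis_unit`, `excitation_nm`, `dose_Jm2`,
#' `hours`, `n_trp`), then columns `x,y`.
#'
#' @param path File path.
#' @return [read_spectrum_csv()] returns a [spectrum()];
#'   `write_spectrum_csv` returns `path` invisibly.
#' @export
read_spectrum_csv <- function(path) {
  r <- read_headered_csv(path, c("x", "y"))
  unit <- if (identical(r$meta$axis_unit, "cm-1")) "cm-1" else "nm"
  meta <- r$meta[setdiff(names(r$meta), "axis_unit")]
  if (!is.null(meta$n_trp)) meta$n_trp <- as.integer(meta$n_trp)
  if (!is.null(meta$normalized))
    meta$normalized <- identical(meta$normalized, "TRUE") ||
      identical(meta$normalized, 1)
  spectrum(r$data$x, r$data$y, unit = unit, meta = meta)
}

#' @param spec A [spectrum()].
#' @rdname read_spectrum_csv
#' @export
write_spectrum_csv <- function(spec, path) {
  meta <- c(list(axis_unit = spec$unit), spec$meta)
  write_headered_csv(data.frame(x = spec$axis, y = spec$intensity),
                     meta, path)
}

#' Read / write a titration CSV
#'
#' Format: `# protein_uM=...`, `# mode=forward|reverse|anisotropy`, then
#' columns `total_ligand_uM,signal`.
#'
#' @param path File path.
#' @return A [titration_series()]; the writer returns `path` invisibly.
#' @export
read_titration_csv <- function(path) {
  r <- read_headered_csv(path, c("total_ligand_uM", "signal"))
  mode <- if (is.null(r$meta$mode)) "forward" else r$meta$mode
  titration_series(r$data$total_ligand_uM, r$data$signal,
                   protein_uM = if (is.null(r$meta$protein_uM)) NA_real_
                                else r$meta$protein_uM,
                   mode = mode)
}

#' @param series A [titration_series()].
#' @rdname read_titration_csv
#' @export
write_titration_csv <- function(series, path) {
  write_headered_csv(
    data.frame(total_ligand_uM = series$conc, signal = series$signal),
    list(protein_uM = if (is.finite(series$protein_uM))
           series$protein_uM else NULL,
         mode = series$mode),
    path)
}

#' Read / write an unfolding-curve CSV
#'
#' Columns `urea_M,ratio_337_350`, optional `# temperature_K=` line.
#'
#' @param path File path.
#' @return An [unfolding_curve()]; the writer returns `path` invisibly.
#' @export
read_unfolding_csv <- function(path) {
  r <- read_headered_csv(path, c("urea_M", "ratio_337_350"))
  tk <- if (is.null(r$meta$temperature_K)) 298.15 else r$meta$temperature_K
  unfolding_curve(r$data$urea_M, r$data$ratio_337_350, temperature_K = tk)
}

#' @param curve An [unfolding_curve()].
#' @rdname read_unfolding_csv
#' @export
write_unfolding_csv <- function(curve, path) {
  write_headered_csv(
    data.frame(urea_M = curve$urea_M, ratio_337_350 = curve$ratio),
    list(temperature_K = curve$temperature_K), path)
}

#' Read / write a quenching CSV
#'
#' Columns `quencher_M,f0_over_f`.
#' @param path File path.
#' @return A [quench_series()]; the writer returns `path` invisibly.
#' @export
read_quench_csv <- function(path) {
  r <- read_headered_csv(path, c("quencher_M", "f0_over_f"))
  quench_series(r$data$quencher_M, r$data$f0_over_f)
}

#' @param q A [quench_series()].
#' @rdname read_quench_csv
#' @export
write_quench_csv <- function(q, path) {
  write_headered_csv(
    data.frame(quencher_M = q$quencher_conc, f0_over_f = q$f0_over_f),
    list(), path)
}

#' Read promoters from FASTA
#'
#' Sequences are uppercased; only A/C/G/T/N are accepted (U and IUPAC
#' ambiguity codes other than N are rejected with the offending record
#' named). Record order is preserved.
#'
#' @param path FASTA file.
#' @return List of [promoter_record()] objects.
#' @export
read_promoters <- function(path) {
  if (!file.exists(path))
    abort_uvf(sprintf("file not found: %s", path), "uvf_io_error")
  set <- Biostrings::readBStringSet(path)
  lapply(seq_along(set), function(i)
    promoter_record(names(set)[i], as.character(set[[i]])))
}

#' Write promoters to FASTA
#'
#' @param records List of [promoter_record()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_promoters <- function(records, path) {
  seqs <- Biostrings::DNAStringSet(
    vapply(records, function(r) r$sequence, character(1)))
  names(seqs) <- vapply(records, function(r) r$id, character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Write motif hits as BED-like TSV
#'
#' Six BED columns (promoter id, 0-based half-open start/end, motif id,
#' score ".", strand) plus a `tss_pos` column with the TSS-relative
#' upstream position.
#'
#' @param hits Hit table from [scan_motifs()].
#' @param promoter The scanned [promoter_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_tsv <- function(hits, promoter, path) {
  bed <- data.frame(chrom = promoter$id,
                    start = hits$start - 1L,
                    end = hits$end,
                    name = hits$motif_id,
                    score = ".",
                    strand = hits$strand,
                    tss_pos = hits$upstream_pos)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

known_config_keys <- c("stages", "out_dir", "seed", "log_level", "on_error")
known_stage_types <- c("simulate_unfolding", "unfold_fit", "bisans_fit",
                       "aniso_fit", "quench_fit", "motif_scan",
                       "scatter_summary", "dls_summary")

#' Read and validate a pipeline configuration
#'
#' YAML document with keys `stages` (list of stage blocks, each with a
#' `stage` type), `out_dir`, `seed`, `log_level`, `on_error`
#' (`"abort"`/`"continue"`). Unknown top-level keys and unknown stage
#' types are rejected before any execution.
#'
#' @param path YAML file.
#' @return Validated config list of class `uvf_run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  unknown <- setdiff(names(cfg), known_config_keys)
  if (length(unknown))
    abort_uvf(sprintf("unknown config key(s): %s",
                      paste(unknown, collapse = ", ")),
              "uvf_config_error")
  if (is.null(cfg$stages) || !length(cfg$stages))
    abort_uvf("config must declare at least one stage", "uvf_config_error")
  for (st in cfg$stages) {
    if (is.null(st$stage) || !st$stage %in% known_stage_types)
      abort_uvf(sprintf("unknown stage '%s' (known: %s)",
                        if (is.null(st$stage)) "<missing>" else st$stage,
                        paste(known_stage_types, collapse = ", ")),
                "uvf_config_error")
  }
  if (is.null(cfg$out_dir)) cfg$out_dir <- "."
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$on_error)) cfg$on_error <- "abort"
  structure(cfg, class = "uvf_run_config")
}

run_stage <- function(st, cfg) {
  name <- if (!is.null(st$name)) st$name else st$stage
  seed <- if (!is.null(st$seed)) st$seed else cfg$seed
  switch(st$stage,
    simulate_unfolding = {
      gc <- generator_config(seed = seed,
                             noise_sd = if (is.null(st$noise_sd)) 0
                                        else st$noise_sd)
      curve <- gen_unfolding_curve(st$model, st$params, cfg = gc)
      out <- file.path(cfg$out_dir, paste0(name, ".csv"))
      write_unfolding_csv(curve, out)
      list(n_points = length(curve$urea_M), file = out, seed = seed)
    },
    unfold_fit = {
      curve <- read_unfolding_csv(st$csv)
      fit <- if (identical(st$model, "two_state")) fit_two_state(curve)
             else fit_three_state(curve)
      res <- list(model = fit$model, params = as.list(fit$params),
                  se = as.list(fit$se), r2 = fit$r2,
                  c_half = as.numeric(fit$c_half), flags = fit$flags)
      if (fit$model == "three_state") res$dG_total <- fit$dG_total
      res
    },
    bisans_fit = {
      cal <- calibrate_reverse(read_titration_csv(st$reverse_csv))
      fwd <- read_titration_csv(st$forward_csv)
      sc <- to_scatchard(fwd, cal)
      fit <- scatchard_fit(sc$v, sc$v_over_s)
      list(phi = cal$phi, n = fit$n, kd_uM = fit$kd, r2 = fit$r2,
           points_used = fit$points_used, dropped = sc$dropped)
    },
    aniso_fit = {
      ser <- read_titration_csv(st$csv)
      fit <- fit_isotherm(ser$conc, ser$signal,
                          offset_mode = if (is.null(st$offset)) "zero"
                                        else st$offset)
      list(bmax = fit$bmax, kd_nM = fit$kd_nM, r2 = fit$r2)
    },
    quench_fit = {
      fit <- stern_volmer_fit(read_quench_csv(st$csv))
      list(ksv = fit$ksv, intercept = fit$intercept, r2 = fit$r2,
           nonphysical = fit$nonphysical)
    },
    motif_scan = {
      proms <- read_promoters(st$fasta)
      all_hits <- lapply(proms, function(p) {
        hits <- scan_motifs(p, st$motifs,
                            strand_mode = if (is.null(st$strand_mode))
                              "forward" else st$strand_mode)
        out <- file.path(cfg$out_dir,
                         paste0(name, "_", p$id, "_hits.tsv"))
        write_hits_tsv(hits, p, out)
        list(promoter = p$id, n_hits = nrow(hits),
             upstream_pos = hits$upstream_pos, file = out)
      })
      list(promoters = length(proms), hits = all_hits)
    },
    scatter_summary = {
      r <- read_headered_csv(st$csv, c("time_min", "od360"))
      scatter_summary(aggregation_trace(r$data$time_min, r$data$od360))
    },
    dls_summary = {
      r <- read_headered_csv(st$csv, c("rh_nm", "intensity_frac"))
      dls_summary(dls_distribution(r$data$rh_nm, r$data$intensity_frac))
    })
}

#' Run a multi-stage analysis pipeline
#'
#' Executes the configured stages in declared order, each random stage
#' consuming its own named seed, and writes a JSON report with per-stage
#' fitted parameters, flags and provenance (input hashes, seeds, package
#' version). Re-running with an identical config and inputs reproduces
#' identical parameter values.
#'
#' @param config Path to a YAML config or a validated config list.
#' @param report_path Optional path for the JSON report (default
#'   `out_dir/report.json`).
#' @return The report, invisibly.
#' @export
run_pipeline <- function(config, report_path = NULL) {
  cfg <- if (is.character(config)) read_run_config(config)
         else validate_run_config(config)
  if (!dir.exists(cfg$out_dir))
    dir.create(cfg$out_dir, recursive = TRUE)
  inputs <- unique(unlist(lapply(cfg$stages, function(st)
    unlist(st[intersect(names(st),
                        c("csv", "fasta", "forward_csv", "reverse_csv"))]))))
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  stages_out <- list()
  for (st in cfg$stages) {
    name <- if (!is.null(st$name)) st$name else st$stage
    res <- tryCatch(
      list(status = "ok", result = run_stage(st, cfg)),
      error = function(e)
        list(status = "error", message = conditionMessage(e)))
    stages_out[[name]] <- res
    if (res$status == "error" && !identical(cfg$on_error, "continue"))
      break
  }
  report <- list(
    package = "uvfoldkit",
    version = as.character(packageVersion("uvfoldkit")),
    seed = cfg$seed,
    input_md5 = hashes,
    stages = stages_out)
  out <- if (is.null(report_path)) file.path(cfg$out_dir, "report.json")
         else report_path
  jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(report)
}
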