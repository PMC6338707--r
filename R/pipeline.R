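#' Reconstruct circular amplicons end to end
#'
#' Runs the whole short-read reconstruction on one tumor sample:
#' amplified-segment selection from the log2R tail, adjacency detection,
#' the three boundary SV-evidence scans, boundary-graph construction,
#' simple-cycle enumeration/deduplication/filtering, per-structure copy
#' number from SNV allele ratios (segments unique to one candidate), and,
#' when linked reads are supplied, barcode-sharing validation of every
#' candidate.
#'
#' @param segments segment table (`dm_segments`, log2r filled).
#' @param tumor_aln tumor alignments (`dm_alignments`).
#' @param reference named `DNAStringSet`.
#' @param params a [dm_params()] object.
#' @param snvs optional tumor SNV table (`dm_snvs`) for copy-number
#'   estimation.
#' @param linked_aln optional barcode-tagged linked-read alignments.
#' @param avg_molecule_length bp; required when `linked_aln` is given.
#' @param genes optional gene table (`chrom`, `start`, `end`, `name`).
#' @return A `dm_reconstruction` object.
#' @export
reconstruct_amplicons <- function(segments, tumor_aln, reference,
                                  params = dm_params(), snvs = NULL,
                                  linked_aln = NULL,
                                  avg_molecule_length = NULL,
                                  genes = NULL) {
  amplified <- select_amplified_segments(segments, params)
  if (!nrow(amplified)) stop("no amplified segments above the cutoff")
  adjacent <- find_adjacent_pairs(amplified, params)
  sv <- collect_sv_evidence(tumor_aln, amplified, reference, params)
  graph <- build_boundary_graph(amplified, sv, adjacent)
  cycles <- find_candidate_cycles(graph, params)
  report <- report_structures(cycles, graph, genes)
  cn <- NULL
  if (!is.null(snvs) && length(cycles)) {
    seg_use <- table(unlist(lapply(cycles, `[[`, "segment_ids")))
    assigned <- assign_snvs_to_segments(snvs, amplified)
    cn <- lapply(seq_along(cycles), function(i) {
      uniq <- cycles[[i]]$segment_ids[
        seg_use[as.character(cycles[[i]]$segment_ids)] == 1]
      if (!length(uniq)) return(NULL)
      s <- assigned[assigned$segment_id %in% uniq, , drop = FALSE]
      br <- select_amplified_alt_branch(s)
      if (!nrow(br$upper)) return(NULL)
      est <- tryCatch(
        estimate_copies_from_ratios(br$upper,
                                    target = sprintf("cycle%d", i),
                                    min_depth = params$min_snv_depth),
        error = function(e) NULL)
      est
    })
    names(cn) <- sprintf("cycle%d", seq_along(cycles))
  }
  validation <- NULL
  if (!is.null(linked_aln) && length(cycles)) {
    if (is.null(avg_molecule_length))
      stop("avg_molecule_length required for linked-read validation")
    validation <- lapply(cycles, validate_cycle_paths, graph = graph,
                         aln = linked_aln,
                         avg_molecule_length = avg_molecule_length,
                         params = params)
  }
  structure(list(amplified = amplified, adjacent = adjacent, sv = sv,
                 graph = graph, cycles = cycles, report = report,
                 cn = cn, validation = validation, params = params),
            class = "dm_reconstruction")
}

#' @export
print.dm_reconstruction <- function(x, ...) {
  cat(sprintf("amplicon reconstruction: %d amplified segments (cutoff %.3g), %d SVs, %d candidate cycles\n",
              nrow(x$amplified), attr(x$amplified, "cutoff"), nrow(x$sv),
              length(x$cycles)))
  if (length(x$cycles)) {
    for (i in seq_along(x$cycles)) {
      v <- if (!is.null(x$validation)) x$validation[[i]]$verdict
      else NA
      cnl <- if (!is.null(x$cn) && !is.null(x$cn[[i]]))
        sprintf(", ~%.0f copies/cell", x$cn[[i]]$copies_per_cell) else ""
      cat(sprintf("  %s (%s bp%s%s)\n",
                  cycle_structure_string(x$cycles[[i]]),
                  format(x$cycles[[i]]$total_length, big.mark = ","),
                  cnl,
                  if (!is.na(v)) paste0("; linked-read ", v) else ""))
    }
  }
  invisible(x)
}

#' @export
summary.dm_reconstruction <- function(object, ...) {
  x <- object
  sv_both <- sum(x$sv$softclip_count > 0 & x$sv$discordant_count > 0)
  sv_disc <- sum(x$sv$softclip_count == 0 & x$sv$discordant_count > 0)
  sv_bridge <- sum(x$sv$softclip_count == 0 & x$sv$discordant_count == 0 &
                     x$sv$bridging_count > 0)
  out <- list(n_amplified = nrow(x$amplified),
              cutoff = attr(x$amplified, "cutoff"),
              n_adjacent = nrow(x$adjacent),
              n_sv = nrow(x$sv), n_sv_softclip_discordant = sv_both,
              n_sv_discordant_only = sv_disc,
              n_sv_bridging_only = sv_bridge,
              n_cycles = length(x$cycles),
              n_validated = if (!is.null(x$validation))
                sum(vapply(x$validation, `[[`, "", "verdict") ==
                      "validated") else NA_integer_,
              n_invalidated = if (!is.null(x$validation))
                sum(vapply(x$validation, `[[`, "", "verdict") ==
                      "invalidated") else NA_integer_)
  class(out) <- "summary.dm_reconstruction"
  out
}

#' @export
print.summary.dm_reconstruction <- function(x, ...) {
  cat(sprintf(
    "%d amplified segments (log2R cutoff %.3g), %d adjacent pairs\n",
    x$n_amplified, x$cutoff, x$n_adjacent))
  cat(sprintf(
    "%d SVs: %d soft-clip+discordant, %d discordant-only, %d bridging-only\n",
    x$n_sv, x$n_sv_softclip_discordant, x$n_sv_discordant_only,
    x$n_sv_bridging_only))
  cat(sprintf("%d candidate circular structures", x$n_cycles))
  if (!is.na(x$n_validated))
    cat(sprintf(" (%d validated, %d invalidated by linked reads)",
                x$n_validated, x$n_invalidated))
  cat("\n")
  invisible(x)
}

#' Run the pipeline from files
#'
#' File-level orchestrator: reads the segment table, alignments,
#' reference (and optional SNV/linked-read inputs), runs
#' [reconstruct_amplicons()] and writes stage reports plus a manifest
#' (package version, effective parameters, input checksums) into
#' `out_dir`.
#'
#' @param config named list (or path to a JSON file) with elements
#'   `segments`, `tumor`, `reference`, and optionally `normal`, `snvs`,
#'   `linked`, `avg_molecule_length`, `params` (named list of
#'   [dm_params()] overrides), `segments_dialect`.
#' @param out_dir output directory.
#' @return the `dm_reconstruction`, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  params <- do.call(dm_params, config$params %||% list())
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  segments <- read_segment_table(config$segments,
                                 dialect = config$segments_dialect %||%
                                   "onebased")
  tumor <- read_alignments(config$tumor, barcode_tag = params$barcode_tag)
  reference <- Biostrings::readDNAStringSet(config$reference)
  names(reference) <- sub("\\s.*", "", names(reference))
  snvs <- if (!is.null(config$snvs)) read_snv_table(config$snvs)
  linked <- if (!is.null(config$linked))
    read_alignments(config$linked, barcode_tag = params$barcode_tag)
  res <- reconstruct_amplicons(segments, tumor, reference, params,
                               snvs = snvs, linked_aln = linked,
                               avg_molecule_length =
                                 config$avg_molecule_length)
  write_report(res$amplified, file.path(out_dir, "amplified_segments.tsv"),
               "tsv", sort_by = "id")
  write_report(res$adjacent, file.path(out_dir, "adjacent_pairs.tsv"),
               "tsv")
  write_report(res$sv, file.path(out_dir, "sv_evidence.tsv"), "tsv")
  write_report(res$report, file.path(out_dir, "structures.tsv"), "tsv",
               sort_by = "structure")
  if (!is.null(res$cn)) {
    cntab <- do.call(rbind, lapply(Filter(Negate(is.null), res$cn),
                                   as.data.frame))
    if (!is.null(cntab))
      write_report(cntab, file.path(out_dir, "copy_number.tsv"), "tsv")
  }
  if (!is.null(res$validation)) {
    vtab <- data.frame(
      structure = vapply(res$validation, `[[`, "", "structure"),
      verdict = vapply(res$validation, `[[`, "", "verdict"))
    write_report(vtab, file.path(out_dir, "validation.tsv"), "tsv")
  }
  inputs <- unlist(config[intersect(names(config),
                                    c("segments", "tumor", "normal",
                                      "snvs", "linked", "reference"))])
  manifest <- list(
    package = "circamp",
    version = as.character(utils::packageVersion("circamp")),
    params = unclass(params),
    inputs = as.list(tools::md5sum(inputs)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
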