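#' Read a raw Ct table into per-sample panel records
#'
#' The Ct table is a long CSV with columns `sample_id`, `marker_set` (1 or
#' 2), `gene`, `ct`. An empty `ct` field encodes an undetected reaction.
#' Every sample must carry an ACTB row in each marker set; target genes
#' must belong to the configured panel and sit in their configured marker
#' set. Sample order follows first appearance in the file.
#'
#' @param path CSV file path (or a data.frame already in that layout).
#' @param panel panel definition (see [default_panel()]).
#' @return list of `ct_panel_record` objects; each holds `sample_id` and,
#'   per marker set, a named Ct vector for its five genes plus `actb_ct`
#'   (`NA` = undetected).
#' @export
read_ct_table <- function(path, panel = default_panel()) {
  check_panel(panel)
  tab <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(ct = "numeric"))
  need <- c("sample_id", "marker_set", "gene", "ct")
  if (!all(need %in% names(tab)))
    stop("Ct table must have columns ", paste(need, collapse = ", "), call. = FALSE)
  tab$ct <- as.numeric(tab$ct)
  if (any(!is.na(tab$ct) & tab$ct <= 0))
    stop("detected Ct values must be positive", call. = FALSE)

  bad <- !(tab$gene %in% c(panel$gene, ACTB))
  if (any(bad))
    stop(sprintf("unknown gene '%s' at row %d (sample %s)",
                 tab$gene[bad][1L], which(bad)[1L], tab$sample_id[bad][1L]),
         call. = FALSE)
  key <- paste(tab$sample_id, tab$marker_set, tab$gene)
  if (anyDuplicated(key))
    stop(sprintf("duplicate entry for sample %s gene %s",
                 tab$sample_id[duplicated(key)][1L],
                 tab$gene[duplicated(key)][1L]), call. = FALSE)
  set_of <- stats::setNames(panel$marker_set, panel$gene)
  tgt <- tab$gene != ACTB
  wrong <- tgt & tab$marker_set != set_of[tab$gene]
  if (any(wrong))
    stop(sprintf("gene %s listed under marker set %s (sample %s)",
                 tab$gene[wrong][1L], tab$marker_set[wrong][1L],
                 tab$sample_id[wrong][1L]), call. = FALSE)

  ids <- unique(tab$sample_id)
  records <- lapply(ids, function(id) {
    d <- tab[tab$sample_id == id, , drop = FALSE]
    sets <- lapply(1:2, function(s) {
      ds <- d[d$marker_set == s, , drop = FALSE]
      actb <- ds$ct[ds$gene == ACTB]
      if (length(actb) == 0L)
        stop(sprintf("missing ACTB row for sample %s marker set %d", id, s),
             call. = FALSE)
      genes <- panel$gene[panel$marker_set == s]
      ct <- stats::setNames(rep(NA_real_, length(genes)), genes)
      hit <- ds$gene %in% genes
      ct[ds$gene[hit]] <- ds$ct[hit]
      list(ct = ct, actb_ct = actb[1L])
    })
    structure(list(sample_id = id, marker_set_1 = sets[[1L]],
                   marker_set_2 = sets[[2L]]),
              class = "ct_panel_record")
  })
  records
}

#' Sample adequacy decision
#'
#' A specimen yields enough amplifiable DNA only if the ACTB reference
#' amplifies in both marker sets at or below a Ct cutoff; otherwise the
#' sample is discarded from analysis as inadequate DNA.
#'
#' @param record a `ct_panel_record`.
#' @param actb_max_ct maximum acceptable ACTB Ct (cycles), boundary
#'   inclusive. Default 40.
#' @return list with `valid` (logical) and `reason` ("" when valid).
#' @export
validate_sample <- function(record, actb_max_ct = 40) {
  stopifnot(inherits(record, "ct_panel_record"))
  a1 <- record$marker_set_1$actb_ct
  a2 <- record$marker_set_2$actb_ct
  ok <- !is.na(a1) && !is.na(a2) && a1 <= actb_max_ct && a2 <= actb_max_ct
  list(valid = ok, reason = if (ok) "" else "inadequate DNA")
}

#' Quantify a sample's methylation profile
#'
#' For each panel gene, delta-Ct is the gene's Ct minus the ACTB Ct of its
#' own marker set; the gene's calibration curve converts delta-Ct to
#' percent methylation (undetected target = 0%). The cumulative
#' methylation score CM is the sum of the ten per-gene percents, so CM
#' lives in \[0, 1000\] CM units.
#'
#' @param record a valid `ct_panel_record`.
#' @param curves named list of `calibration_curve`, one per panel gene.
#' @param panel panel definition.
#' @return list with `sample_id`, `per_gene_percent` (named, panel order)
#'   and `cm`.
#' @export
quantify_profile <- function(record, curves, panel = default_panel()) {
  stopifnot(inherits(record, "ct_panel_record"))
  check_panel(panel)
  missing_curve <- setdiff(panel$gene, names(curves))
  if (length(missing_curve))
    stop("no calibration curve for gene(s): ",
         paste(missing_curve, collapse = ", "), call. = FALSE)
  pct <- vapply(seq_len(nrow(panel)), function(i) {
    g <- panel$gene[i]
    set <- if (panel$marker_set[i] == 1L) record$marker_set_1 else record$marker_set_2
    dct <- set$ct[[g]] - set$actb_ct
    percent_methylation(curves[[g]], dct)
  }, numeric(1L))
  names(pct) <- panel$gene
  list(sample_id = record$sample_id, per_gene_percent = pct, cm = sum(pct))
}

#' Quantify a whole cohort
#'
#' Applies adequacy validation then profile quantitation to each record,
#' keeping the filter ledger consistent: every input record appears in the
#' output, invalid ones with `valid = FALSE` and no CM.
#'
#' @inheritParams quantify_profile
#' @param records list of `ct_panel_record` from [read_ct_table()].
#' @param actb_max_ct ACTB adequacy cutoff (cycles).
#' @return data.frame with `sample_id`, one percent column per gene, `cm`,
#'   `valid`, `invalid_reason`.
#' @export
quantify_cohort <- function(records, curves, panel = default_panel(),
                            actb_max_ct = 40) {
  rows <- lapply(records, function(rec) {
    v <- validate_sample(rec, actb_max_ct)
    if (v$valid) {
      p <- quantify_profile(rec, curves, panel)
      c(list(sample_id = rec$sample_id), as.list(p$per_gene_percent),
        list(cm = p$cm, valid = TRUE, invalid_reason = ""))
    } else {
      pct <- stats::setNames(as.list(rep(NA_real_, nrow(panel))), panel$gene)
      c(list(sample_id = rec$sample_id), pct,
        list(cm = NA_real_, valid = FALSE, invalid_reason = v$reason))
    }
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

#' Write a profile table
#'
#' TSV with sample_id, one percent column per gene, cm, valid and
#' invalid_reason; percents and CM rendered to one decimal place.
#'
#' @param profiles data.frame from [quantify_cohort()].
#' @param path output TSV path.
#' @export
write_profiles <- function(profiles, path) {
  out <- profiles
  num <- vapply(out, is.numeric, logical(1L))
  out[num] <- lapply(out[num], function(x) ifelse(is.na(x), NA, round(x, 1)))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
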