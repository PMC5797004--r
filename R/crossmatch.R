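# Cross-matching of in vitro and in vivo miRNA differential-expression
# results into one concordant table, plus ranking utilities.

#' Cross-match two miRNA differential-expression tables
#'
#' Retains miRNAs that pass the filter in both studies with the same
#' fold-change sign, reporting both log2 fold changes and the in vivo
#' adjusted p-value (the in vivo comparison is the headline result the
#' concordant table is built around; see the vignette). Strict sign
#' agreement is required, so a zero fold change is never concordant.
#'
#' @param deInvitro,deInvivo DE tables from \code{\link{runDE}} for the in
#'   vitro and in vivo study respectively.
#' @param params a \linkS4class{DEFilterParams} applied to both inputs.
#' @return data.frame with columns \code{mirna}, \code{log2fc_invitro},
#'   \code{log2fc_invivo}, \code{adj_p}, \code{direction}, ordered by
#'   in vivo log2FC ascending. Empty (with a message) when no miRNA is
#'   concordant.
#' @export
crossMatch <- function(deInvitro, deInvivo, params = DEFilterParams()) {
  a <- deFilter(deInvitro, params)
  b <- deFilter(deInvivo, params)
  m <- merge(a[c("feature", "log2fc")],
             b[c("feature", "log2fc", "adj_p")],
             by = "feature", suffixes = c("_invitro", "_invivo"))
  m <- m[sign(m$log2fc_invitro) == sign(m$log2fc_invivo) &
           m$log2fc_invitro != 0, , drop = FALSE]
  out <- data.frame(mirna = m$feature,
                    log2fc_invitro = m$log2fc_invitro,
                    log2fc_invivo = m$log2fc_invivo,
                    adj_p = m$adj_p,
                    direction = ifelse(m$log2fc_invivo > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  out <- out[order(out$log2fc_invivo, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out)) message("cross-match: no concordant significant miRNAs")
  out
}

#' Top-k records by fold change in one study
#'
#' Stable sort of a cross-matched table by the chosen fold-change column;
#' ties are broken by miRNA id (lexicographic).
#'
#' @param records a cross-matched table (from \code{\link{crossMatch}} or
#'   \code{\link{crossMatchedMirnaTable}}).
#' @param column \code{"invitro"} or \code{"invivo"}.
#' @param order \code{"asc"} or \code{"desc"}.
#' @param k number of records to return.
#' @return the top-k rows.
#' @export
rankExtremes <- function(records, column = c("invitro", "invivo"),
                         order = c("asc", "desc"), k) {
  column <- match.arg(column)
  order <- match.arg(order)
  col <- paste0("log2fc_", column)
  if (!col %in% names(records)) stop("records lack column '", col, "'")
  if (k < 0) stop("k must be >= 0")
  o <- if (order == "asc")
    base::order(records[[col]], records$mirna)
  else
    base::order(-records[[col]], records$mirna)
  out <- records[o, , drop = FALSE][seq_len(min(k, nrow(records))), ,
                                    drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Published cross-matched sunitinib-resistance miRNA table
#'
#' The packaged transcription of a published table of 36 miRNAs
#' differentially expressed between sunitinib-sensitive and resistant
#' renal-cancer models, concordant between the in vitro and in vivo
#' arms. Used as a fixture for the ranking and cross-matching operations.
#'
#' @return data.frame with columns \code{mirna}, \code{log2fc_invitro},
#'   \code{log2fc_invivo}, \code{adj_p}.
#' @export
crossMatchedMirnaTable <- function() {
  path <- system.file("extdata", "sunitinib_crossmatched_mirnas.tsv",
                      package = "miRTarNet", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}
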