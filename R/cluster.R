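#' Greedy identity clustering of proteins into OTUs
#'
#' Reimplements cd-hit's greedy incremental strategy with exact dynamic-
#' programming alignment instead of word filtering: records are sorted by
#' length (descending; ties by id), and each record joins the first existing
#' cluster whose representative it matches at or above the identity threshold,
#' otherwise it founds a new cluster and becomes its representative. Identity
#' is computed from a global alignment with the shorter-sequence denominator
#' (cd-hit's convention). The default threshold, 0.82, is the level at which
#' proteorhodopsin protein OTUs are defined.
#'
#' OTU labels are assigned after clustering, ordered by descending cluster
#' size then representative id (OTU01, OTU02, ...).
#'
#' @param records nonempty list of \code{protein_record}.
#' @param identity_threshold fraction in (0, 1].
#' @param denominator identity convention, see \code{\link{percent_identity}}.
#' @param ... passed to \code{\link{global_align}}.
#' @return object of class \code{"otu_clustering"}: list with
#'   \code{assignments} (data.frame member_id, otu_id, representative_id,
#'   identity) and \code{clusters} (named list of member id vectors).
#' @export
cluster_greedy <- function(records, identity_threshold = 0.82,
                           denominator = "shorter_seq", ...) {
  if (length(records) == 0L) stop("invalid input: no records to cluster")
  if (identity_threshold <= 0 || identity_threshold > 1)
    stop("identity_threshold must be in (0, 1]")
  if (inherits(records, "protein_record")) records <- list(records)
  ids <- vapply(records, function(r) r$id, "")
  if (anyDuplicated(ids)) stop("duplicate record ids")
  lens <- vapply(records, function(r) nchar(r$sequence), 0L)
  ord <- order(-lens, ids)
  records <- records[ord]; ids <- ids[ord]

  reps <- list()              # representatives in founding order
  member_rep <- character(0); member_idn <- numeric(0); member_id <- character(0)
  for (k in seq_along(records)) {
    rec <- records[[k]]
    assigned <- FALSE
    for (r in reps) {
      aln <- global_align(rec, r, ...)
      idn <- percent_identity(aln, denominator)
      if (idn >= identity_threshold) {
        member_id <- c(member_id, rec$id)
        member_rep <- c(member_rep, r$id)
        member_idn <- c(member_idn, idn)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps[[length(reps) + 1L]] <- rec
      member_id <- c(member_id, rec$id)
      member_rep <- c(member_rep, rec$id)
      member_idn <- c(member_idn, 1.0)
    }
  }

  rep_ids <- vapply(reps, function(r) r$id, "")
  sizes <- vapply(rep_ids, function(r) sum(member_rep == r), 0L)
  lab_ord <- order(-sizes, rep_ids)
  otu_ids <- stats::setNames(sprintf("OTU%02d", seq_along(rep_ids)), rep_ids[lab_ord])

  assignments <- data.frame(member_id = member_id,
                            otu_id = unname(otu_ids[member_rep]),
                            representative_id = member_rep,
                            identity = member_idn,
                            stringsAsFactors = FALSE)
  assignments <- assignments[order(assignments$otu_id, assignments$member_id), ]
  rownames(assignments) <- NULL
  clusters <- split(assignments$member_id, assignments$otu_id)
  structure(list(assignments = assignments, clusters = clusters,
                 identity_threshold = identity_threshold),
            class = "otu_clustering")
}

#' @export
print.otu_clustering <- function(x, ...) {
  cat(sprintf("<otu_clustering> %d records in %d OTUs at >= %.0f%% identity\n",
              nrow(x$assignments), length(x$clusters), 100 * x$identity_threshold))
  sizes <- vapply(x$clusters, length, 0L)
  for (o in names(x$clusters))
    cat(sprintf("  %s: %d member(s), representative %s\n", o, sizes[[o]],
                x$assignments$representative_id[match(o, x$assignments$otu_id)]))
  invisible(x)
}

#' Look up the OTU and representative of a clustered record
#'
#' @param clustering an \code{\link{cluster_greedy}} result.
#' @param query_id record id.
#' @return list(otu_id, representative_id).
#' @export
map_members_to_representative <- function(clustering, query_id) {
  i <- match(query_id, clustering$assignments$member_id)
  if (is.na(i)) stop("not found: '", query_id, "' was not clustered")
  list(otu_id = clustering$assignments$otu_id[i],
       representative_id = clustering$assignments$representative_id[i])
}

#' Write cluster assignments and a per-OTU summary to TSV
#' @param clustering an \code{otu_clustering}.
#' @param path assignments TSV path; the summary is written alongside with
#'   suffix \code{"_summary.tsv"}.
#' @export
write_clusters <- function(clustering, path) {
  utils::write.table(clustering$assignments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  summ <- data.frame(otu_id = names(clustering$clusters),
                     size = vapply(clustering$clusters, length, 0L),
                     representative_id = vapply(names(clustering$clusters), function(o)
                       clustering$assignments$representative_id[
                         match(o, clustering$assignments$otu_id)], ""),
                     row.names = NULL, stringsAsFactors = FALSE)
  utils::write.table(summ, sub("\\.tsv$", "_summary.tsv", path), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
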