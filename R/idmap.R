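# Reconciliation of gene identifiers between two annotation versions from
# precomputed evidence tables: synteny anchors first, orthogroups second.

#' Assemble mapping evidence
#'
#' @param anchors Data frame of syntenic anchor pairs: `idA`, `idB` and
#'   optionally `block`.
#' @param orthogroups Data frame of orthogroup membership: `gene_id`,
#'   `version` (`"A"` or `"B"`), `orthogroup`.
#' @param distances Data frame of pairwise distances: `idA`, `idB`,
#'   `distance` (>= 0).
#' @return List of class `mapping_evidence`.
#' @export
mapping_evidence <- function(anchors, orthogroups, distances) {
  stopifnot(all(c("idA", "idB") %in% names(anchors)),
            all(c("gene_id", "version", "orthogroup") %in% names(orthogroups)),
            all(c("idA", "idB", "distance") %in% names(distances)))
  stopifnot(all(orthogroups$version %in% c("A", "B")),
            all(distances$distance >= 0))
  if (anyDuplicated(orthogroups$gene_id))
    stop("gene ids must be unique within the orthogroup table")
  structure(list(anchors = anchors, orthogroups = orthogroups,
                 distances = distances), class = "mapping_evidence")
}

#' Reconcile gene ids across annotation versions
#'
#' Tier 1 (`synteny_1to1`): anchor pairs in which both ids occur in exactly
#' one anchor; genes in several anchors (tandem arrays) are demoted to the
#' orthogroup tiers rather than guessed. Tier 2 (`orthogroup_1to1`):
#' orthogroups containing exactly one still-unmapped gene of each version.
#' Tier 3 (`orthogroup_best`): remaining version-A genes map to the
#' minimum-distance version-B partner within their orthogroup (ties broken by
#' lexicographic idB); with no finite distance to any partner the gene is left
#' unmapped. Every version-A gene appears exactly once in the output.
#'
#' @param ev A [mapping_evidence()].
#' @return Data frame of class `id_mapping`: `idA`, `idB` (NA when unmapped),
#'   `confidence` in `{synteny_1to1, orthogroup_1to1, orthogroup_best,
#'   unmapped}`, `distance` (NA unless tier 3 or available).
#' @export
reconcile <- function(ev) {
  og <- ev$orthogroups
  ids_a <- sort(unique(c(og$gene_id[og$version == "A"], ev$anchors$idA)))
  og_of <- setNames(og$orthogroup, og$gene_id)
  b_in_og <- split(og$gene_id[og$version == "B"], og$orthogroup[og$version == "B"])
  dist_key <- paste(ev$distances$idA, ev$distances$idB)
  dist_of <- setNames(ev$distances$distance, dist_key)
  lookup_dist <- function(a, b) {
    d <- dist_of[paste(a, b)]
    unname(ifelse(is.na(d), dist_of[paste(b, a)], d))
  }
  out <- data.frame(idA = ids_a, idB = NA_character_,
                    confidence = "unmapped", distance = NA_real_,
                    stringsAsFactors = FALSE)
  rownames(out) <- ids_a
  # tier 1: strict 1:1 anchors
  an <- ev$anchors
  ca <- table(an$idA); cb <- table(an$idB)
  t1 <- an[ca[an$idA] == 1 & cb[an$idB] == 1, , drop = FALSE]
  out[t1$idA, "idB"] <- t1$idB
  out[t1$idA, "confidence"] <- "synteny_1to1"
  out[t1$idA, "distance"] <- lookup_dist(t1$idA, t1$idB)
  mapped_b <- t1$idB
  # tier 2: orthogroups with exactly one unmapped gene of each version
  unm_a <- out$idA[out$confidence == "unmapped"]
  unm_a_og <- unm_a[!is.na(og_of[unm_a])]
  for (grp in unique(og_of[unm_a_og])) {
    a_here <- unm_a_og[og_of[unm_a_og] == grp]
    b_here <- setdiff(b_in_og[[grp]], mapped_b)
    if (length(a_here) == 1L && length(b_here) == 1L) {
      out[a_here, "idB"] <- b_here
      out[a_here, "confidence"] <- "orthogroup_1to1"
      out[a_here, "distance"] <- lookup_dist(a_here, b_here)
      mapped_b <- c(mapped_b, b_here)
    }
  }
  # tier 3: min-distance partner within the orthogroup
  unm_a <- out$idA[out$confidence == "unmapped"]
  no_og <- unm_a[is.na(og_of[unm_a])]
  if (length(no_og))
    warning(length(no_og), " gene(s) without orthogroup left unmapped")
  for (a in setdiff(unm_a, no_og)) {
    cand <- b_in_og[[og_of[[a]]]]
    if (is.null(cand) || !length(cand)) next
    d <- vapply(cand, function(b) {
      dd <- lookup_dist(a, b)
      if (is.na(dd)) Inf else dd
    }, numeric(1))
    if (all(!is.finite(d))) next
    best <- cand[order(d, cand)][1]
    out[a, "idB"] <- best
    out[a, "confidence"] <- "orthogroup_best"
    out[a, "distance"] <- d[[best]]
  }
  rownames(out) <- NULL
  class(out) <- c("id_mapping", "data.frame")
  out
}

#' @export
print.id_mapping <- function(x, ...) {
  cat("id_mapping:", nrow(x), "genes;",
      paste(names(table(x$confidence)), table(x$confidence),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Convert a list of version-A ids using a reconciled mapping
#'
#' @param mapping A [reconcile()] result.
#' @param ids Character vector of version-A ids.
#' @return Data frame `idA`, `idB`, `confidence` (unknown ids are `unmapped`).
#' @export
convert_ids <- function(mapping, ids) {
  m <- mapping[match(ids, mapping$idA), c("idA", "idB", "confidence")]
  m$idA <- ids
  m$confidence[is.na(m$confidence)] <- "unmapped"
  rownames(m) <- NULL
  m
}
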