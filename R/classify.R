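#' Provisional family from domain architecture
#'
#' Only complete domain hits count.  Two AP2 domains give family AP2;
#' one AP2 plus one B3 gives RAV; a single AP2 leaves the protein an
#' unresolved ERF-superfamily candidate; no complete AP2 removes it
#' from the census.  Three or more AP2 domains are provisionally AP2
#' and flagged for review.
#'
#' @param hits hit data.frame from [scan_proteins()]
#' @param protein_ids ids to classify (defaults to ids present in hits)
#' @return data.frame: protein_id, provisional
#'   (`AP2`/`RAV`/`candidate`/`rejected`), evidence, needs_review
#' @export
classify_by_architecture <- function(hits,
                                     protein_ids = unique(hits$protein_id)) {
  out <- lapply(protein_ids, function(id) {
    h <- hits[hits$protein_id == id & hits$complete, , drop = FALSE]
    n_ap2 <- sum(h$model == "AP2")
    n_b3 <- sum(h$model == "B3")
    review <- n_ap2 >= 3L
    if (review)
      warning("protein ", id, " has ", n_ap2,
              " complete AP2 domains; flagged for review")
    prov <-
      if (n_ap2 >= 2L) "AP2"
      else if (n_ap2 == 1L && n_b3 >= 1L) "RAV"
      else if (n_ap2 == 1L) "candidate"
      else "rejected"
    evid <- switch(prov, AP2 = "two_AP2", RAV = "AP2_plus_B3",
                   candidate = "single_AP2", rejected = "")
    data.frame(protein_id = id, provisional = prov, evidence = evid,
               needs_review = review, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Global-alignment similarity between two proteins
#'
#' Needleman-Wunsch with BLOSUM62 and affine gaps; similarity is the
#' percentage of alignment columns (gap columns included) whose residue
#' pair has a positive BLOSUM62 score ("positives").
#'
#' @param a,b protein sequences
#' @param gap_open,gap_ext affine gap costs
#' @return similarity percentage in \[0, 100\]
#' @export
global_similarity <- function(a, b, gap_open = 10, gap_ext = 1) {
  ia <- protein_to_idx(a); ib <- protein_to_idx(b)
  B <- blosum62()
  S <- matrix(0, length(ia), length(ib))
  ok_a <- !is.na(ia); ok_b <- !is.na(ib)
  S[ok_a, ok_b] <- B[ia[ok_a], ib[ok_b], drop = FALSE]
  res <- .affine_align_cpp(S, gap_open, gap_ext, FALSE)
  pos <- 0L
  for (k in seq_along(res$a_idx)) {
    i <- res$a_idx[k]; j <- res$b_idx[k]
    if (i > 0 && j > 0 && !is.na(ia[i]) && !is.na(ib[j]) &&
        B[ia[i], ib[j]] > 0) pos <- pos + 1L
  }
  100 * pos / length(res$a_idx)
}

#' Resolve family and group of single-AP2-domain candidates
#'
#' Order of evidence: (1) Soloist if the best full-length similarity to
#' a Soloist reference reaches `soloist_threshold`; (2) AP2 rescue if
#' the nearest reference by patristic distance in the joint domain tree
#' is an AP2 anchor; (3) otherwise the group of the nearest group
#' reference (DREB for groups I-IV, ERF for V-X, VI-L, Xb-L); (4) group
#' `"single"` when the nearest and second-nearest references belong to
#' different groups and their patristic distances differ by less than
#' `ambiguity_margin` (relative).
#'
#' @param candidate_ids ids of unresolved single-domain proteins
#' @param full_seqs named full-length sequences (candidates)
#' @param refs reference set from [make_reference_set()]
#' @param tree joint NJ tree containing all candidates and references
#' @param soloist_threshold full-length similarity percentage
#' @param ambiguity_margin relative patristic-distance margin
#' @return data.frame: protein_id, family, group, evidence
#' @export
resolve_group <- function(candidate_ids, full_seqs, refs, tree,
                          soloist_threshold = 60,
                          ambiguity_margin = 0.1) {
  need <- c(DREB_GROUPS, setdiff(ERF_GROUPS, NA))
  have <- unique(refs$group[refs$family %in% c("DREB", "ERF")])
  if (length(setdiff(need, have)) > 0)
    stop("reference set lacks group(s): ",
         paste(setdiff(need, have), collapse = ", "))
  if (!any(refs$family == "Soloist"))
    stop("reference set lacks a Soloist anchor")

  pd <- patristic_distances(tree)
  sol_refs <- refs[refs$family == "Soloist", ]
  anchor_refs <- refs[refs$family != "RAV", ]  # RAV is architectural only

  out <- lapply(candidate_ids, function(id) {
    sims <- vapply(sol_refs$full_seq, global_similarity, 0,
                   a = full_seqs[[id]])
    if (max(sims) >= soloist_threshold)
      return(data.frame(protein_id = id, family = "Soloist",
                        group = NA_character_,
                        evidence = "soloist_homology",
                        stringsAsFactors = FALSE))
    dd <- pd[id, intersect(anchor_refs$id, colnames(pd))]
    dd <- sort(dd)
    nearest <- anchor_refs[match(names(dd)[1], anchor_refs$id), ]
    if (nearest$family == "AP2")
      return(data.frame(protein_id = id, family = "AP2",
                        group = NA_character_,
                        evidence = "ap2_rescue,tree_anchor",
                        stringsAsFactors = FALSE))
    grp <- nearest$group
    # nearest reference of a *different* group, for the near-tie rule
    other <- which(anchor_refs$group[match(names(dd), anchor_refs$id)] !=
                     grp)[1]
    if (!is.na(other)) {
      d1 <- dd[1]; d2 <- dd[other]
      if ((d2 - d1) < ambiguity_margin * max(d1, .Machine$double.eps))
        return(data.frame(protein_id = id, family = "ERF",
                          group = "single",
                          evidence = "ambiguous_sister,tree_anchor",
                          stringsAsFactors = FALSE))
    }
    fam <- if (grp %in% DREB_GROUPS) "DREB" else "ERF"
    data.frame(protein_id = id, family = fam, group = grp,
               evidence = "tree_anchor", stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Classify a proteome end to end
#'
#' Runs the domain scan, architecture rules, joint domain alignment and
#' NJ tree with the labelled references, and group resolution.
#'
#' @param proteins named character vector of protein sequences
#' @param refs reference set from [make_reference_set()]
#' @param pssms list of AP2/B3 models (default [default_pssms()])
#' @param p_threshold scan p-value threshold
#' @param ... passed to [resolve_group()]
#' @return list with `assignments` (data.frame: protein_id, family,
#'   group, evidence), `hits`, `tree`, `domain_alignment`
#' @export
classify_proteins <- function(proteins, refs, pssms = default_pssms(),
                              p_threshold = 1e-5, ...) {
  hits <- scan_proteins(proteins, pssms, p_threshold = p_threshold)
  arch <- classify_by_architecture(hits, names(proteins))

  # domain sequence of each candidate = best-scoring complete AP2 hit
  best_domain <- function(id) {
    h <- hits[hits$protein_id == id & hits$model == "AP2" & hits$complete, ]
    h <- h[which.max(h$score_bits), ]
    substr(proteins[[id]], h$start + 1L, h$end)
  }
  cand <- arch$protein_id[arch$provisional == "candidate"]
  assignments <- arch[, c("protein_id", "evidence")]
  assignments$family <- NA_character_
  assignments$group <- NA_character_
  assignments$family[arch$provisional == "AP2"] <- "AP2"
  assignments$family[arch$provisional == "RAV"] <- "RAV"
  assignments$family[arch$provisional == "rejected"] <- "rejected"

  tree <- NULL; aln <- NULL
  if (length(cand) > 0) {
    dom <- vapply(cand, best_domain, "")
    all_dom <- c(dom, setNames(refs$domain_seq, refs$id))
    aln <- progressive_align(all_dom)
    tree <- nj_tree(alignment_distances(aln, "poisson"))
    res <- resolve_group(cand, proteins, refs, tree, ...)
    m <- match(res$protein_id, assignments$protein_id)
    assignments$family[m] <- res$family
    assignments$group[m] <- res$group
    assignments$evidence[m] <- paste(assignments$evidence[m],
                                     res$evidence, sep = ",")
  }
  assignments <- assignments[, c("protein_id", "family", "group",
                                 "evidence")]
  list(assignments = assignments, hits = hits, tree = tree,
       domain_alignment = aln)
}

#' Census of family and group counts
#'
#' @param assignments data.frame with `family` and `group` columns
#'   (rejected proteins are excluded)
#' @return list with `family` (named counts over AP2, DREB, ERF, RAV,
#'   Soloist), `dreb_groups`, `erf_groups` (including `Xb-L` and
#'   `single`, printing 0 where empty), `total`, and the identities
#'   `dreb_total`, `erf_total`
#' @export
census <- function(assignments) {
  a <- assignments[!is.na(assignments$family) &
                     assignments$family != "rejected", ]
  fam_levels <- c("AP2", "DREB", "ERF", "RAV", "Soloist")
  fam <- table(factor(a$family, levels = fam_levels))
  dreb <- table(factor(a$group[a$family == "DREB"], levels = DREB_GROUPS))
  erf_levels <- c(ERF_GROUPS, "single")
  erf <- table(factor(a$group[a$family == "ERF"], levels = erf_levels))
  list(family = setNames(as.integer(fam), fam_levels),
       dreb_groups = setNames(as.integer(dreb), DREB_GROUPS),
       erf_groups = setNames(as.integer(erf), erf_levels),
       dreb_total = sum(dreb), erf_total = sum(erf),
       total = sum(fam))
}

#' Published-style census table shipped with the package
#'
#' Per-group counts for three species, as printed in a genome-wide
#' census of this superfamily; used for the census-identity arithmetic.
#'
#' @return data.frame: family, group, one count column per species
#' @export
reference_census <- function() {
  f <- system.file("extdata", "reference_census_counts.tsv",
                   package = "tfcensus", mustWork = TRUE)
  read.delim(f, check.names = FALSE, na.strings = "NA")
}

#' Census identities on a per-group count table
#'
#' Computes, per species column, the family total, the DREB subfamily
#' total (groups I-IV) and the ERF subfamily total (groups V-X, VI-L,
#' Xb-L, single).
#'
#' @param counts data.frame as returned by [reference_census()]
#' @return data.frame: species, dreb_total, erf_total, grand_total
#' @export
census_identities <- function(counts = reference_census()) {
  species <- setdiff(names(counts), c("family", "group"))
  out <- lapply(species, function(sp) {
    x <- counts[[sp]]
    data.frame(species = sp,
               dreb_total = sum(x[counts$family == "DREB"]),
               erf_total = sum(x[counts$family == "ERF"]),
               grand_total = sum(x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
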