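# Per-species presence/absence calls, lineage calls under the >= 3-species
# rule, contamination screening, and Dollo-parsimony loss mapping.

#' Screen a CDS for bacterial contamination
#'
#' Translated comparison of the CDS against a labelled reference panel.
#' The verdict is positive iff the best-scoring panel member is bacterial
#' and its bit score exceeds the best animal reference's by at least
#' `margin` (fraction of the bacterial bit score), mirroring the published
#' case of an apparent GULO annotation with high homology to a bacterial
#' CDS.
#'
#' @param cds Nucleotide CDS string.
#' @param panel Named CDS vector with a `label` attribute or accompanying
#'   `labels` argument.
#' @param labels Character vector (`"animal"` / `"bacterial"`, one per
#'   panel entry).
#' @param margin Required relative bit-score excess (default 0.10).
#' @param params [search_params()] supplying Karlin-Altschul constants.
#' @return List: `contaminated` (logical), `best_label`, `best_id`,
#'   per-member `bits`.
#' @export
screen_contamination <- function(cds, panel, labels, margin = 0.10,
                                 params = search_params()) {
  stopifnot(length(panel) == length(labels))
  if (!any(labels == "animal") || !any(labels == "bacterial"))
    stop("panel must contain at least one animal and one bacterial reference")
  prot <- sub("\\*$", "", translate_frame(cds, 1L))
  bits <- vapply(panel, function(ref) {
    rp <- sub("\\*$", "", translate_frame(ref, 1L))
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(gsub("\\*", "X", prot)),
      Biostrings::AAString(gsub("\\*", "X", rp)),
      type = "local", substitutionMatrix = .blosum62(),
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
    (params$karlin_lambda * Biostrings::score(pa) - log(params$karlin_k)) /
      log(2)
  }, numeric(1))
  best <- which.max(bits)
  best_animal <- max(bits[labels == "animal"])
  contaminated <- labels[best] == "bacterial" &&
    bits[best] - best_animal >= margin * bits[best]
  list(contaminated = contaminated, best_label = labels[best],
       best_id = names(panel)[best], bits = bits)
}

#' Call GULO presence/absence for one species' assembly evidence
#'
#' Decision precedence: (1) an acceptable HWAK model not flagged as
#' contamination gives PRESENT; (2) only contaminated model(s) give
#' CONTAMINATION; (3) HSP evidence scattered over at least `scatter_min`
#' scaffolds with no single-scaffold motif-bearing model gives
#' INCONCLUSIVE; (4) no HSPs, or residual total query coverage below
#' `residual_max`, gives ABSENT; (5) anything else is INCONCLUSIVE.
#'
#' @param species Species label.
#' @param models List of validated `gene_model`s, each optionally carrying
#'   a logical `contaminated` field (see [screen_contamination()]).
#' @param hsps HSP data frame from [search_genome()] (may have zero rows).
#' @param query Query protein string (for coverage).
#' @param scatter_min Scaffold count that counts as "scattered" (default 3;
#'   the published criterion says only "many").
#' @param residual_max Query-coverage fraction below which homology is
#'   "residual" (default 0.25; unstated in the published criterion).
#' @return A `species_call` list: `species`, `status`, `evidence`.
#' @export
call_species <- function(species, models, hsps, query, scatter_min = 3L,
                         residual_max = 0.25) {
  cov <- 0
  if (nrow(hsps) > 0L) {
    iv <- unique(unlist(lapply(seq_len(nrow(hsps)), function(i)
      seq(hsps$q_start[i], hsps$q_end[i] - 1L))))
    cov <- length(iv) / nchar(query)
  }
  n_scaffolds <- length(unique(hsps$scaffold_id))
  is_contam <- vapply(models, function(m) isTRUE(m$contaminated), logical(1))
  motif_ok <- vapply(models, function(m) m$motif != "none", logical(1))
  acceptable <- vapply(models, function(m) isTRUE(m$acceptable), logical(1))
  hwak <- vapply(models, function(m) identical(m$motif, "HWAK"), logical(1))
  best <- NULL
  status <- if (any(acceptable & hwak & !is_contam)) {
    best <- models[[which(acceptable & hwak & !is_contam)[1]]]
    "PRESENT"
  } else if (length(models) > 0L && all(is_contam)) {
    best <- models[[1]]
    "CONTAMINATION"
  } else if (nrow(hsps) > 0L && n_scaffolds >= scatter_min &&
             !any(motif_ok & acceptable & !is_contam)) {
    "INCONCLUSIVE"
  } else if (nrow(hsps) == 0L || cov < residual_max) {
    "ABSENT"
  } else {
    "INCONCLUSIVE"
  }
  structure(list(species = species, status = status,
                 evidence = list(best_model = best, hsp_coverage = cov,
                                 n_hsp_scaffolds = n_scaffolds,
                                 n_models = length(models),
                                 contaminated_models = sum(is_contam))),
            class = "species_call")
}

#' Call GULO presence/absence for a lineage
#'
#' A lineage is PRESENT if any member species is PRESENT; ABSENT only if at
#' least `min_absent` member species are ABSENT and none is PRESENT (the
#' published rule requires no ortholog with all expected features in at
#' least three species); otherwise INCONCLUSIVE.  CONTAMINATION calls count
#' as neither present nor absent.
#'
#' @param calls List of `species_call`s (>= 1).
#' @param lineage Lineage label.
#' @param min_absent Minimum ABSENT species for an ABSENT call (default 3).
#' @return A `lineage_call` list: `lineage`, `status`, `n_present`,
#'   `n_absent`, `calls`.
#' @export
call_lineage <- function(calls, lineage = "lineage", min_absent = 3L) {
  stopifnot(length(calls) >= 1L)
  st <- vapply(calls, `[[`, character(1), "status")
  status <- if (any(st == "PRESENT")) "PRESENT"
    else if (sum(st == "ABSENT") >= min_absent) "ABSENT"
    else "INCONCLUSIVE"
  structure(list(lineage = lineage, status = status,
                 n_present = sum(st == "PRESENT"),
                 n_absent = sum(st == "ABSENT"), calls = calls),
            class = "lineage_call")
}

# tips below each node, as a list indexed by node number
.clade_tips <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  below <- vector("list", n_node)
  for (i in seq_len(n_tip)) below[[i]] <- i
  # postorder over edges guarantees children resolved before parents
  eo <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(eo))) {
    below[[eo[k, 1]]] <- c(below[[eo[k, 1]]], below[[eo[k, 2]]])
  }
  below
}

#' Map minimum independent gene losses on a cladogram (Dollo)
#'
#' Assumes the ancestral state is gene-present (single origin, no regain)
#' and finds the minimum set of loss edges such that every absent tip
#' descends from exactly one loss edge and no present tip descends from
#' any.  Unknown tips are unconstrained.  Each loss is placed canonically
#' on the deepest (most rootward) edge whose clade contains no present tip.
#'
#' @param tree A rooted `phylo` cladogram.
#' @param tip_states Named character vector over the tips with values
#'   `"present"`, `"absent"`, `"unknown"`.
#' @return A `loss_map` list: `tree`, `tip_states`, `n_losses`,
#'   `loss_edges` (rows of `tree$edge`), `loss_clades` (tip labels below
#'   each loss edge).
#' @export
dollo_losses <- function(tree, tip_states) {
  bad <- setdiff(names(tip_states), tree$tip.label)
  if (length(bad)) stop("tip labels not in tree: ", paste(bad, collapse = ", "))
  states <- rep("unknown", length(tree$tip.label))
  names(states) <- tree$tip.label
  states[names(tip_states)] <- tip_states
  stopifnot(all(states %in% c("present", "absent", "unknown")))
  below <- .clade_tips(tree)
  has_present <- vapply(below, function(t)
    any(states[tree$tip.label[t]] == "present"), logical(1))
  has_absent <- vapply(below, function(t)
    any(states[tree$tip.label[t]] == "absent"), logical(1))
  parent_of <- integer(max(tree$edge))
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  loss <- integer(0)
  for (k in seq_len(nrow(tree$edge))) {
    child <- tree$edge[k, 2]
    if (has_present[child] || !has_absent[child]) next
    # deepest loss-free edge: parent clade must contain a present tip
    # (or the parent is the root, whose state is fixed to present)
    par <- tree$edge[k, 1]
    if (par == root || has_present[par]) loss <- c(loss, k)
  }
  structure(list(tree = tree, tip_states = states, n_losses = length(loss),
                 loss_edges = loss,
                 loss_clades = lapply(loss, function(k)
                   tree$tip.label[below[[tree$edge[k, 2]]]])),
            class = "loss_map")
}

.CALL_COLOURS <- c(PRESENT = "green", ABSENT = "red",
                   INCONCLUSIVE = "blue", CONTAMINATION = "orange")

#' Render species calls on a cladogram
#'
#' Annotates every tip with the published colour code: green = present,
#' red = absent, blue = inconclusive, orange = contamination.  Returns a
#' plain-text table and optionally draws the tree.
#'
#' @param tree A `phylo` cladogram whose tips are the species.
#' @param calls List of `species_call`s covering every tip.
#' @param plot If `TRUE`, draw the cladogram with coloured tip labels.
#' @return Data frame with `species`, `status`, `colour` (one row per tip,
#'   in tip order).
#' @export
render_callogram <- function(tree, calls, plot = FALSE) {
  if (length(calls) == 0L) stop("no calls supplied")
  st <- stats::setNames(vapply(calls, `[[`, character(1), "status"),
                        vapply(calls, `[[`, character(1), "species"))
  missing <- setdiff(tree$tip.label, names(st))
  if (length(missing)) stop("calls missing for tips: ",
                            paste(missing, collapse = ", "))
  tab <- data.frame(species = tree$tip.label,
                    status = unname(st[tree$tip.label]),
                    colour = unname(.CALL_COLOURS[st[tree$tip.label]]))
  if (plot) {
    ape::plot.phylo(tree, tip.color = tab$colour, cex = 0.8)
  }
  tab
}

#' Screen one assembly end to end and call the species
#'
#' Runs the whole per-genome pipeline: translated search, flank retrieval,
#' region growing, spliced-model reconstruction per region, contamination
#' screening of every motif-bearing model, and the species call.
#'
#' @param scaffolds Named nucleotide vector (the assembly).
#' @param query Query protein string.
#' @param panel Optional named CDS vector for contamination screening.
#' @param panel_labels Labels (`"animal"`/`"bacterial"`) for `panel`.
#' @param species Species label for the call.
#' @param sparams [search_params()].
#' @param gparams [genemodel_params()].
#' @param min_overlap Region-growing minimum overlap (nt).
#' @return List: `call` (a `species_call`), `models`, `hsps`, `regions`.
#' @export
screen_assembly <- function(scaffolds, query, panel = NULL,
                            panel_labels = NULL, species = "genome",
                            sparams = search_params(),
                            gparams = genemodel_params(),
                            min_overlap = 2500L) {
  hsps <- search_genome(query, scaffolds, sparams)
  regions <- extract_flanked_regions(hsps, scaffolds, sparams$flank)
  regions <- grow_sequences(regions, min_overlap)
  models <- list()
  for (rg in regions) {
    m <- annotate_region(rg, query, gparams)
    if (is.null(m)) next
    if (!is.null(panel) && m$motif != "none") {
      ver <- screen_contamination(m$cds, panel, panel_labels)
      m$contaminated <- ver$contaminated
      m$contamination_hit <- ver$best_id
    } else {
      m$contaminated <- FALSE
    }
    models[[length(models) + 1L]] <- m
  }
  call <- call_species(species, models, hsps, query)
  list(call = call, models = models, hsps = hsps, regions = regions)
}
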