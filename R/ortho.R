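#' Direction-concordant cross-species filtering of shared DEGs
#'
#' A bean gene called up in both genotypes is retained when at least one
#' of its reference-species homologs appears in the reference up list
#' (likewise for down).  Genes whose homologs appear only in the
#' opposite-direction reference list are excluded and reported as
#' discordant; genes with homologs in both reference lists are retained
#' in their own direction but flagged ambiguous.
#'
#' @param shared a `deg_intersection` from [intersect_genotypes()], or a
#'   list with `shared_up` and `shared_down` character vectors.
#' @param map homolog map: data.frame with columns `bean_gene_id`,
#'   `ref_gene_id` (many-to-many).
#' @param ref_up,ref_down reference-species maturation gene ids.
#' @return A list: `shared_up`, `shared_down` (concordant bean genes),
#'   `discordant`, `ambiguous`, and `pairs` (the concordant
#'   bean-to-reference pairs, for pair-level accounting).
#' @export
concordant_shared_sets <- function(shared, map, ref_up, ref_down) {
  if (anyDuplicated(map)) map <- unique(map)
  if (!nrow(map)) {
    warning("empty homolog map: no genes can be compared")
    return(list(shared_up = character(0), shared_down = character(0),
                discordant = character(0), ambiguous = character(0),
                pairs = map[0, ]))
  }
  one_dir <- function(genes, own_ref, other_ref) {
    keep <- character(0); disc <- character(0); amb <- character(0)
    prs <- list()
    for (g in genes) {
      hom <- map$ref_gene_id[map$bean_gene_id == g]
      if (!length(hom)) next
      in_own <- hom[hom %in% own_ref]
      in_other <- hom[hom %in% other_ref]
      if (length(in_own)) {
        keep <- c(keep, g)
        prs[[g]] <- data.frame(bean_gene_id = g, ref_gene_id = in_own,
                               stringsAsFactors = FALSE)
        if (length(in_other)) amb <- c(amb, g)
      } else if (length(in_other)) {
        disc <- c(disc, g)
      }
    }
    list(keep = keep, disc = disc, amb = amb,
         pairs = if (length(prs)) do.call(rbind, prs) else map[0, ])
  }
  up <- one_dir(shared$shared_up, ref_up, ref_down)
  dn <- one_dir(shared$shared_down, ref_down, ref_up)
  pairs <- rbind(up$pairs, dn$pairs)
  rownames(pairs) <- NULL
  list(shared_up = sort(up$keep), shared_down = sort(dn$keep),
       discordant = sort(c(up$disc, dn$disc)),
       ambiguous = sort(c(up$amb, dn$amb)),
       pairs = pairs)
}

#' Assemble the final maturation gene set
#'
#' Deduplicated union of the concordant up and down sets, one record per
#' bean gene with its direction.  A gene appearing in both directions
#' indicates an upstream invariant breach and raises an error.
#'
#' @param shared_up,shared_down concordant bean gene ids from
#'   [concordant_shared_sets()].
#' @return data.frame (gene_id, direction), sorted by gene id; the
#'   numbers of up and down genes are attached as attribute `counts`.
#' @export
final_maturation_set <- function(shared_up, shared_down) {
  both <- intersect(shared_up, shared_down)
  if (length(both))
    stop("gene(s) in both directions: ", paste(both, collapse = ", "))
  out <- data.frame(
    gene_id = c(unique(shared_up), unique(shared_down)),
    direction = c(rep("up", length(unique(shared_up))),
                  rep("down", length(unique(shared_down)))),
    stringsAsFactors = FALSE)
  out <- out[order(out$gene_id), ]
  rownames(out) <- NULL
  attr(out, "counts") <- c(up = length(unique(shared_up)),
                           down = length(unique(shared_down)))
  out
}
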