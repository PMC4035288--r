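#' Stage-II sets: differential expression intersected with concordant CNA
#'
#' Given one G1-vs-G3 mRNA differential result (direction convention:
#' "up" = higher in G3) and the per-grade amplified/deleted gene sets, the
#' four directional intersections are:
#'
#' * `up_amplified_g3` — up-in-G3 genes that are amplified in G3;
#' * `down_deleted_g3` — down-in-G3 genes that are deleted in G3;
#' * `up_amplified_g1` — up-in-G1 genes (i.e. down-in-G3) amplified in G1;
#' * `down_deleted_g1` — down-in-G1 genes (i.e. up-in-G3) deleted in G1.
#'
#' @param de a `sam_de` over mRNA for the G1-vs-G3 contrast
#'   (class_a = G1, class_b = G3).
#' @param cna_g1,cna_g3 lists with `amplified` and `deleted` gene sets
#'   (e.g. from [cna_gene_sets()]).
#' @return list of class `stage2_sets` with the four gene sets.
#' @export
stage2_sets <- function(de, cna_g1, cna_g3) {
  check_g1g3_contrast(de)
  up_g3 <- called_features(de, "up")
  dn_g3 <- called_features(de, "down")
  structure(list(
    up_amplified_g3 = sort(intersect(up_g3, cna_g3$amplified)),
    down_deleted_g3 = sort(intersect(dn_g3, cna_g3$deleted)),
    up_amplified_g1 = sort(intersect(dn_g3, cna_g1$amplified)),
    down_deleted_g1 = sort(intersect(up_g3, cna_g1$deleted))),
    class = "stage2_sets")
}

check_g1g3_contrast <- function(de) {
  stopifnot(inherits(de, "sam_de"))
  if (!identical(unname(de$contrast), c("G1", "G3"))) {
    stop("a G1-vs-G3 contrast (class_a = G1, class_b = G3) is required")
  }
  invisible(de)
}

#' @export
print.stage2_sets <- function(x, ...) {
  cat("<stage2_sets>\n")
  for (nm in names(x)) cat(sprintf("  %-16s %d genes\n", nm, length(x[[nm]])))
  invisible(x)
}

#' Stage-III classes: CNA-backed genes under opposite-direction miRNAs
#'
#' Intersects each stage-II set with the targets of miRNAs moving in the
#' opposite direction, yielding the four directional classes:
#'
#' * class 1 — down-regulated, deleted genes targeted by up-miRNAs in G3;
#' * class 2 — up-regulated, amplified genes targeted by down-miRNAs in G1;
#' * class 3 — up-regulated, amplified genes targeted by down-miRNAs in G3;
#' * class 4 — down-regulated, deleted genes targeted by up-miRNAs in G1.
#'
#' miRNA directions come from the single G1-vs-G3 miRNA contrast; "up in
#' G1" is read as "down in G3". Each class's miRNA set contains the
#' correctly-directed miRNAs with at least one target in the class's gene
#' set. The gene and miRNA signatures are the unions over classes.
#'
#' @param stage2 a [stage2_sets()] result.
#' @param mirna_de a `sam_de` over miRNA for the G1-vs-G3 contrast.
#' @param targets a [target_map()].
#' @return list of class `signature_classes`: `classes` (class1..class4,
#'   each list(genes, mirnas)), `gene_signature`, `mirna_signature`.
#' @export
stage3_classes <- function(stage2, mirna_de, targets) {
  check_g1g3_contrast(mirna_de)
  if (!length(targets)) {
    warning("empty target map: all classes empty")
  }
  up_mir <- called_features(mirna_de, "up")     # up in G3
  dn_mir <- called_features(mirna_de, "down")   # down in G3 = up in G1
  one_class <- function(genes, mirs) {
    tg <- unlist(targets[intersect(mirs, names(targets))], use.names = FALSE)
    cls_genes <- sort(as.character(intersect(genes, tg)))
    cls_mirs <- sort(Filter(function(m) {
      length(intersect(targets[[m]], cls_genes)) > 0
    }, intersect(mirs, names(targets))))
    list(genes = cls_genes, mirnas = as.character(cls_mirs))
  }
  classes <- list(
    class1 = one_class(stage2$down_deleted_g3, up_mir),   # up miRNAs in G3
    class2 = one_class(stage2$up_amplified_g1, up_mir),   # down in G1 = up in G3
    class3 = one_class(stage2$up_amplified_g3, dn_mir),   # down miRNAs in G3
    class4 = one_class(stage2$down_deleted_g1, dn_mir))   # up in G1 = down in G3
  structure(list(
    classes = classes,
    gene_signature = sort(unique(unlist(lapply(classes, `[[`, "genes")))),
    mirna_signature = sort(unique(unlist(lapply(classes, `[[`, "mirnas"))))),
    class = "signature_classes")
}

#' @export
print.signature_classes <- function(x, ...) {
  cat("<signature_classes>\n")
  for (nm in names(x$classes)) {
    cat(sprintf("  %s: %d genes, %d miRNAs\n", nm,
                length(x$classes[[nm]]$genes),
                length(x$classes[[nm]]$mirnas)))
  }
  cat(sprintf("  gene signature: %d genes; miRNA signature: %d miRNAs\n",
              length(x$gene_signature), length(x$mirna_signature)))
  invisible(x)
}

#' Downsize a signature against published reference signatures
#'
#' Keeps the candidate genes appearing in at least one reference signature
#' (candidate intersect union-of-references), with a per-reference
#' membership report.
#'
#' @param candidate character vector (or list(name, genes)) of candidate
#'   signature genes.
#' @param references named list of character vectors, one per reference
#'   signature.
#' @return list of class `signature`: `name`, `genes`, `membership`
#'   (data.frame gene x reference logical columns).
#' @export
downsize_signature <- function(candidate, references) {
  if (is.list(candidate) && !is.null(candidate$genes)) {
    cand_name <- candidate$name
    candidate <- candidate$genes
  } else cand_name <- "candidate"
  if (!length(references)) stop("at least one reference signature required")
  if (is.null(names(references))) {
    names(references) <- paste0("ref", seq_along(references))
  }
  pool <- unique(unlist(references))
  genes <- sort(intersect(candidate, pool))
  membership <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (nm in names(references)) {
    membership[[nm]] <- genes %in% references[[nm]]
  }
  structure(list(name = paste0(cand_name, "_downsized"), genes = genes,
                 membership = membership),
            class = "signature")
}

#' @export
print.signature <- function(x, ...) {
  cat(sprintf("<signature> %s: %d genes\n", x$name, length(x$genes)))
  if (length(x$genes)) cat(" ", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}
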