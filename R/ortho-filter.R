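# Orthogroup copy-number filtering: the ortholog selection rule is
# "single-copy in every listed diploid, duplicated in the focal species",
# which yields unambiguous (paralog pair, reference ortholog) triples for
# Ks estimation.

.check_orthogroup_table <- function(table) {
  need <- c("gene", "species", "orthogroup")
  if (!all(need %in% names(table)))
    stop("orthogroup table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(table$gene))
    stop("gene ids must be unique")
  bad <- !stats::complete.cases(table[, need]) |
    table$gene == "" | table$species == "" | table$orthogroup == ""
  if (any(bad))
    stop("row(s) with missing fields: ", paste(which(bad), collapse = ", "))
  invisible(table)
}

#' Per-species orthogroup copy-number summary
#'
#' Tabulates, over the orthogroups that contain the species, how many gene
#' copies the species has in each, and reports the fractions of
#' single-copy (exactly 1) and duplicated (2 or more) orthogroups.
#'
#' @param table Data frame with columns `gene`, `species`, `orthogroup`.
#' @param species Species id to summarize.
#' @return List with `species`, `n_orthogroups` (denominator),
#'   `distribution` (named vector: copy count -> number of orthogroups),
#'   `fraction_single_copy`, `fraction_duplicated`.
#' @export
copy_number_summary <- function(table, species) {
  .check_orthogroup_table(table)
  rows <- table[table$species == species, , drop = FALSE]
  if (nrow(rows) == 0L)
    stop("species '", species, "' not present in the table")
  counts <- table(rows$orthogroup)
  dist <- table(as.integer(counts))
  list(species = species,
       n_orthogroups = length(counts),
       distribution = stats::setNames(as.integer(dist), names(dist)),
       fraction_single_copy = mean(counts == 1L),
       fraction_duplicated = mean(counts >= 2L))
}

#' Ortholog selection criterion
#'
#' @param diploid_species Character vector of diploid species that must be
#'   single-copy (presence required: an absent species fails the test).
#' @param focal_species The polyploid species required to be duplicated.
#' @param reference_species The diploid whose ortholog is emitted alongside
#'   each focal pair (default: first diploid).
#' @param focal_copies Required focal copy number (default exactly 2, so
#'   downstream pairing is unambiguous).
#' @return Object of class `filter_criterion`.
#' @export
filter_criterion <- function(diploid_species, focal_species,
                             reference_species = diploid_species[1L],
                             focal_copies = 2L) {
  if (length(diploid_species) == 0L) stop("need at least one diploid species")
  if (focal_species %in% diploid_species)
    stop("focal species cannot be in the diploid list")
  if (focal_copies < 2L) stop("'focal_copies' must be >= 2")
  structure(list(diploid_species = as.character(diploid_species),
                 focal_species = focal_species,
                 reference_species = reference_species,
                 focal_copies = as.integer(focal_copies)),
            class = "filter_criterion")
}

#' Select orthogroups single-copy in diploids and duplicated in the focal
#'
#' An orthogroup passes when every diploid in the criterion has exactly one
#' copy and the focal species has exactly `focal_copies` copies. For each
#' passing orthogroup the focal gene pair (sorted by gene id) and the
#' reference species' ortholog are emitted. Passing orthogroups where the
#' reference species is missing (only possible when it is not one of the
#' diploids) are dropped with a warning.
#'
#' @param table Data frame with columns `gene`, `species`, `orthogroup`.
#' @param criterion A [filter_criterion()].
#' @return List with `orthogroups` (passing ids), `triples` (data frame
#'   `orthogroup, focal_gene_1, focal_gene_2, reference_gene`),
#'   `n_input_orthogroups` and the echoed `criterion`.
#' @export
select_orthogroups <- function(table, criterion) {
  stopifnot(inherits(criterion, "filter_criterion"))
  .check_orthogroup_table(table)
  all_ogs <- unique(table$orthogroup)
  if (length(all_ogs) == 0L)
    return(list(orthogroups = character(0),
                triples = data.frame(orthogroup = character(0),
                                     focal_gene_1 = character(0),
                                     focal_gene_2 = character(0),
                                     reference_gene = character(0),
                                     stringsAsFactors = FALSE),
                n_input_orthogroups = 0L, criterion = criterion))

  species_set <- c(criterion$diploid_species, criterion$focal_species)
  sub <- table[table$species %in% species_set, , drop = FALSE]
  cn <- table(factor(sub$orthogroup, levels = all_ogs),
              factor(sub$species, levels = species_set))
  ok_diploid <- rowSums(cn[, criterion$diploid_species, drop = FALSE] == 1L) ==
    length(criterion$diploid_species)
  ok_focal <- cn[, criterion$focal_species] == criterion$focal_copies
  passing <- all_ogs[ok_diploid & ok_focal]

  triples <- lapply(passing, function(og) {
    focal <- sort(table$gene[table$orthogroup == og &
                               table$species == criterion$focal_species])
    ref <- table$gene[table$orthogroup == og &
                        table$species == criterion$reference_species]
    if (length(ref) == 0L) return(NULL)
    data.frame(orthogroup = og, focal_gene_1 = focal[1L],
               focal_gene_2 = focal[2L], reference_gene = ref[1L],
               stringsAsFactors = FALSE)
  })
  dropped <- vapply(triples, is.null, logical(1))
  if (any(dropped)) {
    warning(sum(dropped), " passing orthogroup(s) lack the reference ",
            "species '", criterion$reference_species, "'; dropped")
    passing <- passing[!dropped]
    triples <- triples[!dropped]
  }
  triples <- if (length(triples)) do.call(rbind, triples) else
    data.frame(orthogroup = character(0), focal_gene_1 = character(0),
               focal_gene_2 = character(0), reference_gene = character(0),
               stringsAsFactors = FALSE)
  list(orthogroups = passing, triples = triples,
       n_input_orthogroups = length(all_ogs), criterion = criterion)
}
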