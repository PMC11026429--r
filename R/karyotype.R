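# Symbolic algebra over ancestral crucifer genomic-block karyotypes.
#
# The 22-block convention: blocks A..X with the K-L and M-N associations
# each treated as one block (written KL and MN), and block W split into the
# two halves Wa and Wb. A chromosome is an ordered list of signed blocks
# plus a centromere position (an index 0..n_blocks counting the blocks to
# its left; 0 and n_blocks are terminal). Karyotype text format, one
# chromosome per line:
#
#   ID: [-]BLOCK ... | ... .
#
# where `|` marks the centromere, an optional trailing `.` ends the line
# and `#` starts a comment.

.BLOCK_LABELS <- c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J",
                   "KL", "MN", "O", "P", "Q", "R", "S", "T", "U", "V",
                   "W", "X")

# "-Wa" -> list(label = "W", sub = "a", sign = -1); NULL if malformed
.parse_block_token <- function(tok) {
  m <- regmatches(tok, regexec("^(-?)([A-Z]{1,2})([ab]?)$", tok))[[1]]
  if (length(m) == 0L) return(NULL)
  sign <- if (m[2] == "-") -1L else 1L
  label <- m[3]
  sub <- m[4]
  if (!label %in% .BLOCK_LABELS) return(NULL)
  if (sub != "" && label != "W") return(NULL)
  list(label = label, sub = sub, sign = sign)
}

.block_token <- function(label, sub = "", sign = 1L) {
  paste0(if (sign < 0L) "-" else "", label, sub)
}

.block_label <- function(tokens) {
  sub("^-", "", tokens)
}

.flip_block <- function(tokens) {
  ifelse(grepl("^-", tokens), sub("^-", "", tokens), paste0("-", tokens))
}

#' Chromosome model: ordered signed genomic blocks plus a centromere
#'
#' @param id Chromosome identifier.
#' @param blocks Character vector of signed block tokens (e.g. `"A"`,
#'   `"-Wb"`, `"KL"`).
#' @param centromere Number of blocks to the left of the centromere
#'   (0..length(blocks); 0 and length(blocks) are terminal positions), or
#'   `NA` if unknown.
#' @return Object of class `chromosome_model`.
#' @export
chromosome_model <- function(id, blocks, centromere = NA_integer_) {
  if (length(blocks) < 1L) stop("chromosome '", id, "' needs >= 1 block")
  for (tok in blocks)
    if (is.null(.parse_block_token(tok)))
      stop("chromosome '", id, "': invalid block token '", tok, "'")
  centromere <- as.integer(centromere)
  if (!is.na(centromere) &&
      (centromere < 0L || centromere > length(blocks)))
    stop("chromosome '", id, "': centromere index out of bounds")
  structure(list(id = as.character(id), blocks = as.character(blocks),
                 centromere = centromere),
            class = "chromosome_model")
}

#' Karyotype: a set of chromosome models
#'
#' @param chromosomes List of [chromosome_model()] objects with unique ids.
#' @return Object of class `karyotype`; the haploid number `n` is the
#'   chromosome count.
#' @export
karyotype <- function(chromosomes = list()) {
  for (ch in chromosomes) stopifnot(inherits(ch, "chromosome_model"))
  ids <- vapply(chromosomes, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate chromosome ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  structure(list(chromosomes = stats::setNames(chromosomes, ids)),
            class = "karyotype")
}

#' @export
print.karyotype <- function(x, ...) {
  cat("karyotype: n =", length(x$chromosomes), "\n")
  cat(serialize_karyotype(x), sep = "\n")
  invisible(x)
}

#' Number of chromosomes in a karyotype
#' @param k A `karyotype`.
#' @return Integer haploid number.
#' @export
n_chromosomes <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  length(k$chromosomes)
}

#' Parse a karyotype from its text representation
#'
#' One chromosome per line, `ID: [-]BLOCK[(a|b)] ... | ... .`, where `|`
#' marks the centromere, the trailing `.` is optional and `#` starts a
#' comment. See the package format description for the block alphabet.
#'
#' @param text Character vector of lines, or a single string with
#'   newlines.
#' @return A [karyotype()].
#' @examples
#' k <- parse_karyotype("AK2: D E | .")
#' serialize_karyotype(k)
#' @export
parse_karyotype <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- sub("#.*$", "", lines)
  chroms <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "") next
    m <- regmatches(line, regexec("^([^:[:space:]]+):(.*)$", line))[[1]]
    if (length(m) == 0L)
      stop("line ", ln, ": expected 'ID: blocks...'")
    id <- m[2]
    toks <- strsplit(trimws(m[3]), "[[:space:]]+")[[1]]
    toks <- toks[toks != ""]
    if (length(toks) > 0L && toks[length(toks)] == ".")
      toks <- toks[-length(toks)]
    blocks <- character(0)
    centromere <- NA_integer_
    for (tok in toks) {
      if (tok == "|") {
        if (!is.na(centromere))
          stop("line ", ln, ": more than one centromere")
        centromere <- length(blocks)
        next
      }
      if (is.null(.parse_block_token(tok)))
        stop("line ", ln, ": unknown block label '", tok, "'")
      blocks <- c(blocks, tok)
    }
    chroms[[length(chroms) + 1L]] <-
      chromosome_model(id, blocks, centromere)
  }
  karyotype(chroms)
}

#' Serialize a karyotype to its text representation
#'
#' Inverse of [parse_karyotype()]: `parse(serialize(k))` is the identity.
#'
#' @param k A [karyotype()].
#' @return Character vector, one line per chromosome.
#' @export
serialize_karyotype <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  vapply(k$chromosomes, function(ch) {
    toks <- ch$blocks
    if (!is.na(ch$centromere))
      toks <- append(toks, "|", after = ch$centromere)
    paste0(ch$id, ": ", paste(c(toks, "."), collapse = " "))
  }, character(1), USE.NAMES = FALSE)
}

#' Read or write a karyotype file
#'
#' @param path File path.
#' @return `read_karyotype`: a [karyotype()]. `write_karyotype`: `path`,
#'   invisibly.
#' @rdname karyotype_io
#' @export
read_karyotype <- function(path) {
  parse_karyotype(readLines(path))
}

#' @param k A `karyotype`.
#' @rdname karyotype_io
#' @export
write_karyotype <- function(k, path) {
  writeLines(serialize_karyotype(k), path)
  invisible(path)
}

.PRESET_ACK <- c(
  "# Ancestral Cardamineae karyotype (n = 8).",
  "# Centromeres between the block groups of the two ancestral arms;",
  "# AK8/6 is acrocentric-like with the centromere between P and Wb,",
  "# AK2 has a terminal centromere after E.",
  "AK1: A B | C .",
  "AK2: D E | .",
  "AK3: F G | H .",
  "AK4: I | J .",
  "AK5: KL | MN .",
  "AK6/8: V Wa | Q R .",
  "AK7: S T | U .",
  "AK8/6: O P | Wb X .")

.PRESET_RAQ <- c(
  "# Reconstructed R. aquatica karyotype (n = 15): six homeologous pairs,",
  "# the two unfused homeologues RaChr03 (AK2) and RaChr14 (AK8/6), and",
  "# the RaChr15 fusion chromosome formed by nested chromosome insertion",
  "# of the second AK2 homeologue (inverted) into the centromere of the",
  "# second AK8/6 homeologue.",
  "RaChr01: A B | C .",
  "RaChr02: A B | C .",
  "RaChr03: D E | .",
  "RaChr04: F G | H .",
  "RaChr05: F G | H .",
  "RaChr06: I | J .",
  "RaChr07: I | J .",
  "RaChr08: KL | MN .",
  "RaChr09: KL | MN .",
  "RaChr10: V Wa | Q R .",
  "RaChr11: V Wa | Q R .",
  "RaChr12: S T | U .",
  "RaChr13: S T | U .",
  "RaChr14: O P | Wb X .",
  "RaChr15: O P | -E -D Wb X .")

#' Built-in karyotype presets
#'
#' `"ACK_Cardamineae_n8"`: the eight-chromosome ancestral Cardamineae
#' karyotype (AK1..AK8 block compositions). `"R_aquatica_n15"`: the
#' reconstructed 15-chromosome allotetraploid karyotype (six homeologous
#' pairs, the unfused AK2 and AK8/6 homeologues, and the fusion chromosome
#' carrying O P -E -D Wb X).
#'
#' @param name Preset name.
#' @return A [karyotype()].
#' @export
karyotype_preset <- function(name = c("ACK_Cardamineae_n8",
                                      "R_aquatica_n15")) {
  name <- match.arg(name)
  parse_karyotype(switch(name,
                         ACK_Cardamineae_n8 = .PRESET_ACK,
                         R_aquatica_n15 = .PRESET_RAQ))
}

#' Whole-genome duplication of a karyotype
#'
#' Duplicates every chromosome, suffixing the copies with `_1` and `_2`;
#' the haploid number doubles and the block multiset is exactly doubled.
#'
#' @param k A [karyotype()].
#' @return The duplicated `karyotype`.
#' @export
whole_genome_duplication <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  out <- list()
  for (ch in k$chromosomes) {
    out[[length(out) + 1L]] <-
      chromosome_model(paste0(ch$id, "_1"), ch$blocks, ch$centromere)
    out[[length(out) + 1L]] <-
      chromosome_model(paste0(ch$id, "_2"), ch$blocks, ch$centromere)
  }
  karyotype(out)
}

#' Nested chromosome insertion (NCI)
#'
#' Splices the donor chromosome's full block list into the recipient at
#' the recipient's centromere (which must be internal), removing the donor
#' chromosome: the haploid number decreases by one and the block multiset
#' is conserved. With `donor_orientation = "inverted"` the donor block
#' list is reversed and its signs flipped. The fused chromosome keeps the
#' recipient's id; its centromere is placed at the donor's centromere
#' (mapped through the orientation), reflecting retention of the donor
#' centromere at the insertion site.
#'
#' @param k A [karyotype()].
#' @param recipient_id,donor_id Chromosome ids (must differ).
#' @param donor_orientation `"forward"` or `"inverted"`.
#' @return The post-NCI `karyotype`.
#' @examples
#' k <- whole_genome_duplication(karyotype_preset("ACK_Cardamineae_n8"))
#' k2 <- nested_chromosome_insertion(k, "AK8/6_2", "AK2_2", "inverted")
#' n_chromosomes(k2) # 15
#' @export
nested_chromosome_insertion <- function(k, recipient_id, donor_id,
                                        donor_orientation = c("inverted",
                                                              "forward")) {
  stopifnot(inherits(k, "karyotype"))
  donor_orientation <- match.arg(donor_orientation)
  if (identical(recipient_id, donor_id))
    stop("donor and recipient must differ")
  rec <- k$chromosomes[[recipient_id]]
  don <- k$chromosomes[[donor_id]]
  if (is.null(rec)) stop("no chromosome '", recipient_id, "'")
  if (is.null(don)) stop("no chromosome '", donor_id, "'")
  cpos <- rec$centromere
  if (is.na(cpos) || cpos <= 0L || cpos >= length(rec$blocks))
    stop("recipient '", recipient_id,
         "' centromere is terminal or unknown; NCI needs an internal ",
         "centromere")
  db <- don$blocks
  dcent <- don$centromere
  if (donor_orientation == "inverted") {
    db <- rev(.flip_block(db))
    if (!is.na(dcent)) dcent <- length(db) - dcent
  }
  fused_blocks <- append(rec$blocks, db, after = cpos)
  fused_cent <- if (!is.na(dcent)) cpos + dcent else cpos
  fused <- chromosome_model(rec$id, fused_blocks, fused_cent)
  keep <- k$chromosomes[setdiff(names(k$chromosomes), c(recipient_id,
                                                        donor_id))]
  karyotype(c(keep, list(fused))[order(match(
    c(names(keep), rec$id), names(k$chromosomes)))])
}

#' Invert a block segment of a chromosome
#'
#' Reverses the order of blocks `from..to` and flips their orientation
#' signs. Inverting the same segment twice restores the original. In
#' paracentric mode the segment must not span the centromere.
#'
#' @param chromosome A [chromosome_model()].
#' @param from,to 1-based block indices of the segment.
#' @param paracentric Require the segment to exclude the centromere.
#' @return The modified `chromosome_model`.
#' @export
invert_segment <- function(chromosome, from, to, paracentric = FALSE) {
  stopifnot(inherits(chromosome, "chromosome_model"))
  nb <- length(chromosome$blocks)
  if (from < 1L || to > nb || from > to)
    stop("segment indices out of range")
  cent <- chromosome$centromere
  if (paracentric && !is.na(cent) && cent >= from && cent < to)
    stop("paracentric inversion cannot span the centromere")
  seg <- seq.int(from, to)
  blocks <- chromosome$blocks
  blocks[seg] <- rev(.flip_block(blocks[seg]))
  chromosome_model(chromosome$id, blocks, cent)
}

#' Genomic-block copy numbers of a karyotype
#'
#' Counts each of the 22 blocks across all chromosomes, ignoring
#' orientation. The two halves of block W count half each:
#' count(W) = (count(Wa) + count(Wb)) / 2 (+ any unsplit W). A karyotype is
#' called tetraploid-origin ("duplicated") when every block present has
#' copy number exactly 2.
#'
#' @param k A [karyotype()].
#' @return List with `copy_number` (named numeric over the 22 block
#'   labels) and `tetraploid_call` (logical).
#' @examples
#' block_copy_numbers(karyotype_preset("R_aquatica_n15"))$tetraploid_call
#' @export
block_copy_numbers <- function(k) {
  stopifnot(inherits(k, "karyotype"))
  toks <- .block_label(unlist(lapply(k$chromosomes, `[[`, "blocks"),
                              use.names = FALSE))
  counts <- stats::setNames(numeric(length(.BLOCK_LABELS)), .BLOCK_LABELS)
  plain <- table(toks)
  for (lbl in names(plain)) {
    if (lbl %in% c("Wa", "Wb"))
      counts["W"] <- counts["W"] + plain[[lbl]] / 2
    else
      counts[lbl] <- counts[lbl] + plain[[lbl]]
  }
  present <- counts[counts > 0]
  list(copy_number = counts,
       tetraploid_call = length(present) > 0 && all(present == 2))
}

# order/orientation-insensitive content signature (Wa/Wb kept distinct)
.content_signature <- function(blocks) {
  paste(sort(.block_label(blocks)), collapse = " ")
}

# does `window` of length nd containing exactly the donor content exist
# strictly internal to `labels`? returns TRUE/FALSE
.has_internal_run <- function(labels, donor_labels) {
  nd <- length(donor_labels)
  n <- length(labels)
  if (n < nd + 2L) return(FALSE)
  donor_sig <- paste(sort(donor_labels), collapse = " ")
  for (s in seq.int(2L, n - nd)) {
    win <- labels[seq.int(s, s + nd - 1L)]
    if (paste(sort(win), collapse = " ") == donor_sig) return(TRUE)
  }
  FALSE
}

#' Classify chromosomes against an ancestral karyotype
#'
#' A chromosome is `shared` when its block content equals the content of
#' some ancestral chromosome (order- and orientation-insensitive at block
#' granularity; the Wa/Wb halves match only their own half), so
#' within-chromosome inversions do not affect the call. Each remaining
#' (`derived`) chromosome is tested for the nested-chromosome-insertion
#' signature: its content is the union of two ancestral chromosomes, with
#' the donor's full content contiguous and strictly internal, flanked on
#' both sides by recipient blocks. Detected events report donor and
#' recipient ancestral ids.
#'
#' @param k Karyotype to classify.
#' @param ancestral Ancestral reference karyotype on the same block
#'   alphabet.
#' @return List with `classification` (data frame `chromosome, status,
#'   matches_ancestor`), `events` (data frame `chromosome, kind, donor,
#'   recipient`), `n_shared`, `n_derived`.
#' @examples
#' match_ancestral(karyotype_preset("R_aquatica_n15"),
#'                 karyotype_preset("ACK_Cardamineae_n8"))$n_shared # 14
#' @export
match_ancestral <- function(k, ancestral) {
  stopifnot(inherits(k, "karyotype"), inherits(ancestral, "karyotype"))
  anc_sigs <- vapply(ancestral$chromosomes, function(ch)
    .content_signature(ch$blocks), character(1))
  anc_labels <- lapply(ancestral$chromosomes, function(ch)
    .block_label(ch$blocks))
  anc_ids <- names(ancestral$chromosomes)

  rows <- list()
  events <- list()
  for (ch in k$chromosomes) {
    sig <- .content_signature(ch$blocks)
    hit <- match(sig, anc_sigs)
    if (!is.na(hit)) {
      rows[[length(rows) + 1L]] <-
        data.frame(chromosome = ch$id, status = "shared",
                   matches_ancestor = anc_ids[hit],
                   stringsAsFactors = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <-
      data.frame(chromosome = ch$id, status = "derived",
                 matches_ancestor = NA_character_,
                 stringsAsFactors = FALSE)
    labels <- .block_label(ch$blocks)
    found <- FALSE
    # d == r is allowed: after a WGD the donor may be the recipient's own
    # homeologue, and both then map to the same ancestral chromosome
    for (d in seq_along(anc_ids)) {
      if (found) break
      for (r in seq_along(anc_ids)) {
        combined <- paste(sort(c(anc_labels[[d]], anc_labels[[r]])),
                          collapse = " ")
        if (combined != sig) next
        if (.has_internal_run(labels, anc_labels[[d]])) {
          events[[length(events) + 1L]] <-
            data.frame(chromosome = ch$id, kind = "NCI",
                       donor = anc_ids[d], recipient = anc_ids[r],
                       stringsAsFactors = FALSE)
          found <- TRUE
          break
        }
      }
    }
  }
  classification <- do.call(rbind, rows)
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(chromosome = character(0), kind = character(0),
               donor = character(0), recipient = character(0),
               stringsAsFactors = FALSE)
  list(classification = classification,
       events = events,
       n_shared = sum(classification$status == "shared"),
       n_derived = sum(classification$status == "derived"))
}
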