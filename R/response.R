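# Small response utilities: temporal classification of differentially
# expressed genes across two submergence time points, and the leaf-shape
# dissection index.

#' Call differentially expressed genes from a contrast table
#'
#' Strict thresholds, matching the convention FDR < `fdr_max` and
#' |log2FC| > `min_abs_lfc`: a gene exactly at a threshold is not called.
#'
#' @param table Data frame with columns `gene`, `log2fc`, `fdr`.
#' @param fdr_max FDR threshold (default 0.01).
#' @param min_abs_lfc Absolute log2 fold-change threshold (default 1).
#' @return List with character vectors `up` and `down`.
#' @export
call_degs <- function(table, fdr_max = 0.01, min_abs_lfc = 1) {
  need <- c("gene", "log2fc", "fdr")
  if (!all(need %in% names(table)))
    stop("DEG table needs columns: ", paste(need, collapse = ", "))
  if (fdr_max <= 0 || min_abs_lfc <= 0)
    stop("thresholds must be > 0")
  sig <- !is.na(table$fdr) & table$fdr < fdr_max & !is.na(table$log2fc)
  list(up = table$gene[sig & table$log2fc > min_abs_lfc],
       down = table$gene[sig & table$log2fc < -min_abs_lfc])
}

#' Classify genes by response timing across two time points
#'
#' Set algebra over the genes responding at an early time point (e.g. 1 h
#' of submergence) and a late one (e.g. 4 days): `early` responds only at
#' the first, `throughout` at both, `late` only at the second. The three
#' classes are disjoint and cover the union.
#'
#' @param deg_1h,deg_4d Character vectors of responding gene ids.
#' @return List with character vectors `early`, `throughout`, `late`.
#' @examples
#' classify_timing(c("a", "b"), c("b", "c"))
#' @export
classify_timing <- function(deg_1h, deg_4d) {
  deg_1h <- unique(as.character(deg_1h))
  deg_4d <- unique(as.character(deg_4d))
  list(early = setdiff(deg_1h, deg_4d),
       throughout = intersect(deg_1h, deg_4d),
       late = setdiff(deg_4d, deg_1h))
}

#' Direction-resolved timing classification from two DEG tables
#'
#' Applies [call_degs()] to both contrast tables and [classify_timing()]
#' separately to the up- and down-regulated sets, yielding six classes.
#'
#' @param table_1h,table_4d DEG tables (`gene`, `log2fc`, `fdr`).
#' @param fdr_max,min_abs_lfc Thresholds passed to [call_degs()].
#' @return Nested list `up`/`down`, each with `early`, `throughout`,
#'   `late`, plus a `counts` data frame.
#' @export
deg_timing_report <- function(table_1h, table_4d, fdr_max = 0.01,
                              min_abs_lfc = 1) {
  d1 <- call_degs(table_1h, fdr_max, min_abs_lfc)
  d2 <- call_degs(table_4d, fdr_max, min_abs_lfc)
  up <- classify_timing(d1$up, d2$up)
  down <- classify_timing(d1$down, d2$down)
  counts <- data.frame(
    direction = rep(c("up", "down"), each = 3L),
    class = rep(c("early", "throughout", "late"), 2L),
    n = c(lengths(up), lengths(down)),
    stringsAsFactors = FALSE)
  list(up = up, down = down, counts = counts)
}

#' Leaf-complexity dissection index
#'
#' DI = perimeter / sqrt(area): unit-free, invariant under uniform
#' scaling, and minimized by a circle at 2 * sqrt(pi) ~ 3.545 (the
#' isoperimetric bound). Inputs violating the bound (impossible
#' perimeter/area combinations) draw a warning.
#'
#' @param perimeter,area Positive numeric vectors in consistent length
#'   units (area in those units squared).
#' @return Numeric vector of dissection indices.
#' @examples
#' dissection_index(4, 1)            # unit square: 4
#' dissection_index(2 * pi, pi)      # unit circle: 2 * sqrt(pi)
#' @export
dissection_index <- function(perimeter, area) {
  if (any(perimeter <= 0) || any(area <= 0))
    stop("'perimeter' and 'area' must be > 0")
  bad <- perimeter^2 < 4 * pi * area * (1 - 1e-9)
  if (any(bad))
    warning(sum(bad), " shape(s) violate the isoperimetric bound ",
            "(perimeter^2 >= 4*pi*area); check the measurements")
  perimeter / sqrt(area)
}
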