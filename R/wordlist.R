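# Item reduction for the parent-reported expressive-vocabulary word list.

#' Reduce a word list to its screening-relevant items
#'
#' Applies the two quantitative reduction rules used when shortening a long
#' parent-reported vocabulary checklist into a brief screening word list:
#'
#' 1. **Usage rule** - drop items endorsed ("child says the word") by fewer
#'    than `usage_min` of the children: very rare words carry little signal at
#'    this age.
#' 2. **Item-PPV rule** - treating each item's *non*-endorsement as a
#'    single-item screen, drop items whose positive predictive value for the
#'    deficit outcome is below `item_ppv_min`. When an item is endorsed by
#'    every child the screen-positive set is empty, PPV is undefined, and the
#'    rule is skipped for that item.
#'
#' Age-dependence of item endorsement is not used as a removal rule (it has no
#' quantitative definition here); instead the audit table reports the range of
#' endorsement rates across the 23-25 month age groups so such items can be
#' reviewed manually.
#'
#' @param items An `item_matrix` from [generate_item_matrix()], or a binary
#'   matrix with one column per item.
#' @param outcome Binary deficit labels aligned with the item-matrix rows.
#' @param usage_min Minimum endorsement rate, default 0.25.
#' @param item_ppv_min Minimum single-item PPV, default 0.50.
#' @return A list with `retained` (item labels) and `audit`, a per-item
#'   `data.frame` with columns `item`, `usage`, `item_ppv`,
#'   `dropped_usage`, `dropped_ppv`, `age_usage_range`.
#' @export
reduce_word_list <- function(items, outcome, usage_min = 0.25,
                             item_ppv_min = 0.50) {
  if (inherits(items, "item_matrix")) {
    age <- items$age_months
    mat <- items$items
  } else {
    mat <- as.matrix(items)
    age <- NULL
  }
  if (length(mat) == 0L || nrow(mat) == 0L || ncol(mat) == 0L) {
    stop("empty item matrix", call. = FALSE)
  }
  y <- as.logical(outcome)
  stopifnot(nrow(mat) == length(y))
  if (is.null(colnames(mat))) colnames(mat) <- sprintf("item%03d", seq_len(ncol(mat)))

  usage <- colMeans(mat)
  # screen-positive for item j = child does NOT say word j
  n_pos <- colSums(1 - mat)
  ppv <- ifelse(n_pos > 0, colSums((1 - mat) * y) / n_pos, NA_real_)

  age_range <- if (is.null(age)) {
    rep(NA_real_, ncol(mat))
  } else {
    ages <- sort(unique(age))
    by_age <- matrix(NA_real_, nrow = ncol(mat), ncol = length(ages))
    for (k in seq_along(ages)) {
      by_age[, k] <- colMeans(mat[age == ages[k], , drop = FALSE])
    }
    apply(by_age, 1, function(r) diff(range(r)))
  }

  dropped_usage <- usage < usage_min
  dropped_ppv <- !is.na(ppv) & ppv < item_ppv_min
  audit <- data.frame(item = colnames(mat), usage = usage, item_ppv = ppv,
                      dropped_usage = dropped_usage, dropped_ppv = dropped_ppv,
                      age_usage_range = age_range,
                      row.names = NULL, stringsAsFactors = FALSE)
  list(retained = colnames(mat)[!(dropped_usage | dropped_ppv)], audit = audit)
}
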