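# Cyclic difference sets known to this package, keyed "v-k-lambda".
# Developing a (v, k, lambda) planar/biplane difference set mod v yields a
# symmetric BIBD with b = v blocks and r = k replications.
.difference_sets <- list(
  "7-3-1"  = c(0L, 1L, 3L),          # Fano plane
  "13-4-1" = c(0L, 1L, 3L, 9L),      # projective plane of order 3
  "11-5-2" = c(1L, 3L, 4L, 5L, 9L)   # quadratic residues mod 11
)

#' Construct a balanced incomplete block design by cyclic development
#'
#' Builds the BIBD that assigns attribute triples (more generally,
#' k-subsets) to choice tasks. Construction is by cyclic development of a
#' known difference set: block `i` is `{(d + i) mod v : d in base set}`,
#' for `i = 0, ..., v-1`, giving a symmetric design with `b = v` blocks and
#' replications per treatment equal to the block size. This is
#' deterministic and auditable:
#' repeated calls give identical block lists.
#'
#' The survey design used for the seven nurse-sow attributes is
#' `construct_bibd(7, 3, 1)`: seven tasks of three attributes, every
#' attribute shown three times, every pair co-occurring exactly once.
#'
#' @param v Number of treatments (attributes).
#' @param k Block size (attributes per choice task).
#' @param lam Number of blocks in which each unordered pair co-occurs.
#' @return An object of class `bibd_design`: a list with elements `v`, `b`,
#'   `r`, `k`, `lam` and `blocks` (a list of `b` integer vectors of 0-based
#'   treatment indices, ascending within blocks, in cyclic-development
#'   order).
#' @examples
#' d <- construct_bibd(7, 3, 1)
#' d$blocks[[1]]  # 0 1 3
#' validate_bibd(d)$pass
#' @export
construct_bibd <- function(v, k, lam) {
  v <- as.integer(v); k <- as.integer(k); lam <- as.integer(lam)
  key <- paste(v, k, lam, sep = "-")
  base <- .difference_sets[[key]]
  if (is.null(base)) {
    stop(sprintf(
      paste0("no construction available for (v, k, lambda) = (%d, %d, %d); ",
             "supported parameter triples: %s"),
      v, k, lam, paste(names(.difference_sets), collapse = ", ")
    ), call. = FALSE)
  }
  blocks <- lapply(seq_len(v) - 1L, function(i) sort((base + i) %% v))
  design <- structure(
    list(v = v, b = v, r = k, k = k, lam = lam, blocks = blocks),
    class = "bibd_design"
  )
  report <- validate_bibd(design)
  if (!report$pass) {  # cannot happen for a true difference set
    stop("constructed design failed balance validation", call. = FALSE)
  }
  design
}

#' Validate a block design against the BIBD balance conditions
#'
#' Checks, by direct counting, that every block has exactly `k` distinct
#' members, that each treatment occurs in exactly `r` blocks (equal
#' occurrence), that every unordered pair of treatments co-occurs in exactly
#' `lam` blocks (equal co-occurrence), and that the parameter identities
#' `b*k = v*r` and `lam*(v-1) = r*(k-1)` hold. An unbalanced design yields
#' a failing report, never an error.
#'
#' @param design A `bibd_design`, or any list with fields `v`, `r`, `k`,
#'   `lam` and `blocks` (0-based indices).
#' @return An object of class `bibd_validation`: list with `occurrence`
#'   (per-treatment occurrence vector), `cooccurrence` (v x v matrix of
#'   pair counts), `checks` (named logical vector), and `pass`.
#' @export
validate_bibd <- function(design) {
  v <- design$v
  blocks <- design$blocks
  if (length(blocks) == 0L) stop("design has no blocks", call. = FALSE)
  occurrence <- integer(v)
  cooc <- matrix(0L, v, v)
  block_sizes_ok <- TRUE
  for (bl in blocks) {
    if (length(bl) != design$k || anyDuplicated(bl) ||
        any(bl < 0L | bl >= v)) {
      block_sizes_ok <- FALSE
    }
    idx <- bl + 1L
    occurrence[idx] <- occurrence[idx] + 1L
    if (length(idx) >= 2L) {
      prs <- utils::combn(sort(idx), 2L)
      for (j in seq_len(ncol(prs))) {
        cooc[prs[1L, j], prs[2L, j]] <- cooc[prs[1L, j], prs[2L, j]] + 1L
      }
    }
  }
  cooc <- cooc + t(cooc)
  off_diag <- cooc[upper.tri(cooc)]
  checks <- c(
    block_size      = block_sizes_ok,
    equal_occurrence = all(occurrence == design$r),
    equal_cooccurrence = all(off_diag == design$lam),
    parameter_identities =
      (length(blocks) * design$k == v * design$r) &&
      (design$lam * (v - 1L) == design$r * (design$k - 1L))
  )
  structure(
    list(occurrence = occurrence, cooccurrence = cooc,
         checks = checks, pass = all(checks)),
    class = "bibd_validation"
  )
}

#' @export
print.bibd_design <- function(x, ...) {
  cat(sprintf("Balanced incomplete block design (v,b,r,k,lambda) = (%d,%d,%d,%d,%d)\n",
              x$v, x$b, x$r, x$k, x$lam))
  for (i in seq_along(x$blocks)) {
    cat(sprintf("  task %d: {%s}\n", i, paste(x$blocks[[i]], collapse = ", ")))
  }
  invisible(x)
}

#' @export
print.bibd_validation <- function(x, ...) {
  cat("BIBD validation:", if (x$pass) "PASS" else "FAIL", "\n")
  cat("  occurrence:", paste(x$occurrence, collapse = " "), "\n")
  for (nm in names(x$checks)) {
    cat(sprintf("  %-22s %s\n", nm, if (x$checks[[nm]]) "ok" else "VIOLATED"))
  }
  invisible(x)
}

#' Bind attribute codes to a block design
#'
#' Maps the 0-based treatment indices of a design to attribute codes,
#' producing the concrete choice tasks shown to respondents. The default
#' binding assigns attribute `j` (in the order of `attrs`) to treatment
#' index `j - 1`; an optional permutation reassigns indices.
#'
#' @param design A `bibd_design`.
#' @param attrs A [attribute_set()] with exactly `design$v` rows.
#' @param permutation Optional integer permutation of `1:v`;
#'   `permutation[j]` is the treatment index (1-based) bound to attribute
#'   `j`.
#' @return An object of class `bws_design`: a list with the `design`, the
#'   `attributes` table, and `tasks`, a data frame with columns `task` and
#'   `position_1` ... `position_k` holding attribute codes.
#' @examples
#' bd <- bind_attributes(construct_bibd(7, 3, 1), nurse_sow_attributes())
#' bd$tasks[1, ]  # task 1: SCLH BCS STN
#' @export
bind_attributes <- function(design, attrs, permutation = NULL) {
  if (nrow(attrs) != design$v) {
    stop(sprintf("attribute set has %d entries but design has v = %d",
                 nrow(attrs), design$v), call. = FALSE)
  }
  v <- design$v
  if (is.null(permutation)) permutation <- seq_len(v)
  if (length(permutation) != v || !setequal(permutation, seq_len(v))) {
    stop("`permutation` must be a permutation of 1:v", call. = FALSE)
  }
  # code_for[i] = code bound to treatment index i-1
  code_for <- character(v)
  code_for[permutation] <- attrs$code
  task_mat <- t(vapply(design$blocks,
                       function(bl) code_for[bl + 1L],
                       character(design$k)))
  tasks <- data.frame(task = seq_len(design$b), task_mat,
                      stringsAsFactors = FALSE)
  names(tasks) <- c("task", paste0("position_", seq_len(design$k)))
  structure(
    list(design = design, attributes = attrs, tasks = tasks),
    class = "bws_design"
  )
}

#' @export
print.bws_design <- function(x, ...) {
  cat(sprintf("Bound BWS design: %d tasks of %d attributes (v = %d)\n",
              x$design$b, x$design$k, x$design$v))
  print(x$tasks, row.names = FALSE)
  invisible(x)
}

# Attribute codes of one task as a character vector.
task_codes <- function(bound, task_id) {
  row <- bound$tasks[bound$tasks$task == task_id, , drop = FALSE]
  if (nrow(row) != 1L) {
    stop(sprintf("unknown task id %s", task_id), call. = FALSE)
  }
  as.character(row[1, -1L])
}

#' Write / read a bound design as CSV
#'
#' The CSV has one row per choice task, columns `task_id` and
#' `position_1` ... `position_k` holding attribute codes.
#'
#' @param bound A `bws_design` from [bind_attributes()].
#' @param path File path.
#' @rdname design_io
#' @export
write_design <- function(bound, path) {
  out <- bound$tasks
  names(out)[1L] <- "task_id"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @param attrs Attribute set the file's codes must come from; defaults to
#'   the codes found in the file, in first-appearance order.
#' @rdname design_io
#' @export
read_design <- function(path, attrs = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  pos_cols <- grep("^position_", names(tab), value = TRUE)
  if (!("task_id" %in% names(tab)) || length(pos_cols) < 2L) {
    stop("design file must have columns task_id, position_1..position_k",
         call. = FALSE)
  }
  codes_seen <- unique(unlist(tab[pos_cols], use.names = FALSE))
  if (is.null(attrs)) attrs <- attribute_set(codes_seen)
  unknown <- setdiff(codes_seen, attrs$code)
  if (length(unknown)) {
    stop("unknown attribute codes in design file: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  v <- nrow(attrs)
  k <- length(pos_cols)
  blocks <- lapply(seq_len(nrow(tab)), function(i) {
    sort(match(as.character(tab[i, pos_cols]), attrs$code) - 1L)
  })
  b <- length(blocks)
  r <- as.integer(round(b * k / v))
  design <- structure(
    list(v = v, b = b, r = r, k = k,
         lam = if (v > 1L) as.integer(round(r * (k - 1) / (v - 1))) else 0L,
         blocks = blocks),
    class = "bibd_design"
  )
  bound <- bind_attributes(design, attrs)
  bound$tasks <- {
    t2 <- tab[c("task_id", pos_cols)]
    names(t2)[1L] <- "task"
    t2
  }
  bound
}

#' Printable survey sheet for a bound design
#'
#' Renders the choice tasks as the text a respondent would see: for each
#' task, the attribute labels with columns for marking the most and least
#' important one.
#'
#' @param bound A `bws_design`.
#' @return Character vector of lines, invisibly; printed to the console.
#' @export
survey_sheet <- function(bound) {
  labs <- stats::setNames(bound$attributes$label, bound$attributes$code)
  lines <- character(0)
  for (i in seq_len(nrow(bound$tasks))) {
    codes <- task_codes(bound, bound$tasks$task[i])
    lines <- c(
      lines,
      sprintf("Choice set %s", bound$tasks$task[i]),
      sprintf("  %-35s [Most important] [Least important]", "Attribute"),
      sprintf("  %-35s [    ]           [    ]", labs[codes]),
      ""
    )
  }
  cat(lines, sep = "\n")
  invisible(lines)
}
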