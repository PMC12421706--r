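# Parameter-table plumbing shared by the model builder, the syntax
# exporter/parser and the RAM compiler. One row per model entry:
#   lhs op rhs   with op in "=~", "~", "~~", "~1" (rhs == "" for "~1")
#   free  TRUE for estimated parameters, FALSE for fixed values
#   value fixed value (free = FALSE) or start value (free = TRUE)
#   label equality label; free rows sharing a label share one parameter
#   family semantic tag used by constraint operators
#   i,m,t,s design indices where applicable (NA otherwise)

pt_empty <- function() {
  data.frame(lhs = character(0), op = character(0), rhs = character(0),
             free = logical(0), value = numeric(0), label = character(0),
             family = character(0),
             i = integer(0), m = integer(0), t = integer(0), s = integer(0),
             stringsAsFactors = FALSE)
}

pt_row <- function(lhs, op, rhs, free, value, label = "", family = "",
                   i = NA_integer_, m = NA_integer_, t = NA_integer_,
                   s = NA_integer_) {
  data.frame(lhs = lhs, op = op, rhs = rhs, free = free, value = value,
             label = label, family = family,
             i = as.integer(i), m = as.integer(m), t = as.integer(t),
             s = as.integer(s), stringsAsFactors = FALSE)
}

pt_bind <- function(...) do.call(rbind, list(...))

# locate a row by (lhs, op, rhs); "~~" matches both orientations
pt_match <- function(pt, lhs, op, rhs) {
  hit <- pt$op == op & ((pt$lhs == lhs & pt$rhs == rhs) |
                          (op == "~~" & pt$lhs == rhs & pt$rhs == lhs))
  which(hit)
}

# Equate a set of (free) rows under `label`. Transitive: any row sharing an
# old label of a member joins the group.
pt_equate <- function(pt, idx, label) {
  if (!length(idx)) return(pt)
  old <- unique(pt$label[idx])
  old <- old[nzchar(old)]
  sel <- seq_len(nrow(pt)) %in% idx | (nzchar(pt$label) & pt$label %in% old)
  pt$label[sel & pt$free] <- label
  pt
}

# One parameter id per free row group (shared label = shared id); 0 = fixed.
pt_free_ids <- function(pt) {
  ids <- integer(nrow(pt))
  keys <- ifelse(nzchar(pt$label), pt$label,
                 paste0(".row", seq_len(nrow(pt))))
  keys[!pt$free] <- NA_character_
  ukeys <- unique(keys[pt$free])
  ids[pt$free] <- match(keys[pt$free], ukeys)
  ids
}

pt_n_free <- function(pt) length(unique(pt_free_ids(pt)[pt$free]))

# Display names for the free parameters, in id order. A labeled group is
# named by its label; singletons by "lhs op rhs".
pt_param_names <- function(pt) {
  ids <- pt_free_ids(pt)
  n <- pt_n_free(pt)
  out <- character(n)
  for (k in seq_len(n)) {
    rows <- which(ids == k)
    lab <- pt$label[rows[1]]
    out[k] <- if (nzchar(lab)) lab else {
      r <- rows[1]
      if (pt$op[r] == "~1") paste0(pt$lhs[r], "~1")
      else paste0(pt$lhs[r], pt$op[r], pt$rhs[r])
    }
  }
  out
}

# start-value vector in free-parameter order
pt_start <- function(pt) {
  ids <- pt_free_ids(pt)
  n <- pt_n_free(pt)
  th <- numeric(n)
  for (k in seq_len(n)) th[k] <- pt$value[which(ids == k)[1]]
  th
}
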