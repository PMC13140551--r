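# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validation failures carry class "gillsym_validation" so the command-line
# front end can map them to a dedicated exit code; statistical precondition
# violations (e.g. post hoc test without a significant omnibus) use
# "gillsym_precondition".
stop_gs <- function(..., class = "gillsym_validation") {
  stop(errorCondition(paste0(...), class = c(class, "gillsym_error")))
}

# Resolve a host-group selector to specimen indices. NULL or "combined"
# selects everything; anything else must match at least one specimen.
group_index <- function(host_group, group) {
  if (is.null(group) || identical(group, "combined")) {
    return(seq_along(host_group))
  }
  idx <- which(!is.na(host_group) & host_group == group)
  if (length(idx) == 0L) {
    stop_gs("unknown host group: '", group, "'")
  }
  idx
}

# Canonical label for a set of taxa: members in pool order, joined by "+".
set_label <- function(members, pool) {
  paste(pool[sort(match(members, pool))], collapse = "+")
}

label_members <- function(label) strsplit(label, "+", fixed = TRUE)[[1]]

# All subsets of seq_len(S) with sizes in `sizes`, as a list of integer
# vectors, enumerated in combn order (size-major).
all_subsets <- function(S, sizes) {
  out <- lapply(sizes, function(k) {
    if (k == 0L) return(list())
    asplit(utils::combn(S, k), 2L)
  })
  lapply(unlist(out, recursive = FALSE), as.integer)
}

mask_of <- function(idx, bit) sum(bit[idx])

# Small stable hash of a configuration object, for output headers.
config_hash <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, force = TRUE,
                                     digits = 10))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

pkg_version <- function() as.character(utils::packageVersion("gillsym"))
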