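# Fixture builders: everything is constructed in code.

# Build a presence_matrix directly from a named list
# specimen -> character vector of member taxa.
make_presence <- function(communities, pool, host_group = NULL) {
  if (is.null(names(communities))) {
    names(communities) <- sprintf("s%02d", seq_along(communities))
  }
  m <- matrix(FALSE, length(communities), length(pool),
              dimnames = list(names(communities), pool))
  for (i in seq_along(communities)) m[i, communities[[i]]] <- TRUE
  hg <- rep(NA_character_, length(communities))
  names(hg) <- names(communities)
  if (!is.null(host_group)) hg[] <- host_group
  structure(list(present = m, pool = pool, threshold = 0,
                 host_group = hg),
            class = "presence_matrix")
}

# Presence matrix with a prescribed richness vector in which the pair
# (pool[1], pool[2]) is never observed together: each specimen gets the
# LAST k taxa of the pool, which excludes both whenever k <= S - 2.
make_presence_richness <- function(k, pool) {
  stopifnot(all(k <= length(pool) - 2))
  comms <- lapply(k, function(ki) {
    if (ki == 0) character() else rev(pool)[seq_len(ki)]
  })
  make_presence(comms, pool)
}

# Percent abundance table from a numeric matrix of row-proportions.
make_percent <- function(values, host_group = NULL) {
  abundance_table(values, unit = "percent", host_group = host_group)
}

write_tmp <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}
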