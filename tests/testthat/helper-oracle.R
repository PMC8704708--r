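# Independent brute-force oracles, written with plain loops and their own
# rounding so they share no code path with the package implementation.

# half-up rounding to d decimals / 3 significant figures
oracle_round1 <- function(x) floor(x * 10 + 0.5) / 10
oracle_sig3 <- function(x) {
  if (is.na(x) || x == 0) return(x)
  d <- 2 - floor(log10(abs(x)))
  floor(x * 10^d + 0.5) / 10^d
}
oracle_round <- function(x, cls) {
  if (cls %in% c("proximate", "energy")) oracle_round1(x) else oracle_sig3(x)
}

# Brute-force unification: group records by (foodex2, basis), pool each
# component's measured/trace values (zeros and logical zeros eliminated),
# take the sample median (midpoint of the central pair for even n), round
# by class. Logical zeros are reinstated as chosen 0 where nothing was
# measured. Returns one row per unified value.
oracle_unify <- function(records, registry) {
  v <- records$values
  cls_of <- stats::setNames(registry$component_class, registry$tagname)
  out <- list()
  for (key in unique(paste(v$foodex2, v$basis, sep = "|"))) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    sub <- v[v$foodex2 == parts[1] & v$basis == parts[2], ]
    for (tag in unique(sub$tagname)) {
      vv <- sub[sub$tagname == tag, ]
      pool <- numeric()
      n_lz <- 0L
      for (i in seq_len(nrow(vv))) {
        st <- vv$status[i]
        if (st == "measured") pool <- c(pool, vv$value[i])
        if (st == "trace") pool <- c(pool, 0)
        if (st == "logical_zero") n_lz <- n_lz + 1L
        # st == "zero" and st == "missing": eliminated from the pool
      }
      if (length(pool) > 0L) {
        s <- sort(pool)
        n <- length(s)
        med <- if (n %% 2L == 1L) s[(n + 1L) / 2L] else mean(s[n / 2 + 0:1])
        out[[length(out) + 1L]] <- data.frame(
          foodex2 = parts[1], basis = parts[2], tagname = tag,
          n_sources = n, median = med,
          chosen = oracle_round(med, cls_of[[tag]]),
          stringsAsFactors = FALSE
        )
      } else if (n_lz > 0L) {
        out[[length(out) + 1L]] <- data.frame(
          foodex2 = parts[1], basis = parts[2], tagname = tag,
          n_sources = 0L, median = 0, chosen = 0, stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- do.call(rbind, out)
  res[order(res$foodex2, res$basis, res$tagname), ]
}

# Compare implementation and oracle on one fixture; returns TRUE when every
# chosen/median/n agrees bit-exactly.
unify_matches_oracle <- function(fx, registry = default_registry()) {
  rec <- harmonize_fixture(fx, registry)
  db <- unify_database(rec, registry)
  got <- db$values[order(db$values$foodex2, db$values$basis, db$values$tagname),
                   c("foodex2", "basis", "tagname", "n_sources", "median",
                     "chosen")]
  want <- oracle_unify(rec, registry)
  isTRUE(nrow(got) == nrow(want)) &&
    identical(got$foodex2, want$foodex2) &&
    identical(got$tagname, want$tagname) &&
    identical(as.integer(got$n_sources), as.integer(want$n_sources)) &&
    identical(got$median, want$median) &&
    identical(got$chosen, want$chosen)
}

# small harmonized record set built by hand for unifier unit tests:
# `values` is a list of per-source named value vectors (NA = blank cell)
make_records <- function(per_source, foodex2 = "A0001", group = "vegetables",
                         zero_is_logical = FALSE, registry = default_registry()) {
  recs <- lapply(names(per_source), function(sid) {
    vals <- per_source[[sid]]
    tab <- data.frame(food_id = paste0(sid, "_1"), name = "test food",
                      foodex2 = foodex2, food_group = group,
                      record_class = "generic", stringsAsFactors = FALSE)
    for (tag in names(vals)) tab[[tolower(tag)]] <- vals[[tag]]
    tags <- names(vals)
    mp <- source_mapping(
      source_id = sid,
      columns = data.frame(column = tolower(tags), tagname = tags,
                           unit = resolve_component(registry, tags)$standard_unit),
      id_column = "food_id", foodex2_column = "foodex2",
      name_column = "name", group_column = "food_group",
      record_class_column = "record_class",
      zero_is_logical = zero_is_logical
    )
    ingest_source(tab, mp, registry)
  })
  bind_records(recs)
}
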