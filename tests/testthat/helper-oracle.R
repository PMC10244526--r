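# Independent brute-force contingency enumeration over a cleaned case set,
# written in plain base R loops so it shares no code path with the pipeline's
# join-based counting.
brute_norm <- function(x) tolower(trimws(gsub("[[:space:]]+", " ", x)))

brute_cells <- function(cases, smq_map, group, member_pts,
                        once = FALSE, comparator = "neither") {
  demo <- cases$cases
  case_of <- setNames(demo$case_id, demo$report_id)
  grp_of <- setNames(as.character(demo$exposure_group), demo$case_id)
  pts_by_case <- lapply(
    split(brute_norm(cases$reactions$pt), case_of[cases$reactions$report_id]),
    unique
  )
  member_pts <- brute_norm(member_pts)
  a <- b <- cc <- d <- 0L
  for (cid in names(pts_by_case)) {
    g <- grp_of[[cid]]
    side <- if (g == group) "t"
      else if (comparator == "neither" && g == "neither") "c"
      else if (comparator != "neither" && g != group) "c"
      else NA_character_
    if (is.na(side)) next
    pts <- pts_by_case[[cid]]
    n_in <- sum(pts %in% member_pts)
    n_out <- length(pts) - n_in
    tgt <- if (once) as.integer(n_in > 0) else n_in
    if (side == "t") {
      a <- a + tgt; b <- b + n_out
    } else {
      cc <- cc + tgt; d <- d + n_out
    }
  }
  c(a = a, b = b, c = cc, d = d)
}
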