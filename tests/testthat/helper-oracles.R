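# Independent brute-force rule list, coded directly from the category
# definitions (H above both parents; H below both; H level with one parent
# while the parents differ and the other contrast agrees; H strictly between
# differing parents; nothing significant anywhere; otherwise nearest
# idealised reference, ties to additive). Used only as an oracle against the
# package's decision table.
oracle_classify <- function(s_mp, s_mh, s_ph, M, H, P) {
  if (s_mh == "H>M" && s_ph == "H>P") {
    switch(s_mp, "M>P" = "trans_up_M_gt_P", "M<P" = "trans_up_M_lt_P",
           ns = "trans_up_M_eq_P")
  } else if (s_mh == "H<M" && s_ph == "H<P") {
    switch(s_mp, "M>P" = "trans_down_M_gt_P", "M<P" = "trans_down_M_lt_P",
           ns = "trans_down_M_eq_P")
  } else if (s_mh == "ns" && s_mp == "M>P" && s_ph == "H>P") {
    "ELD_M_high"
  } else if (s_mh == "ns" && s_mp == "M<P" && s_ph == "H<P") {
    "ELD_M_low"
  } else if (s_ph == "ns" && s_mp == "M<P" && s_mh == "H>M") {
    "ELD_P_high"
  } else if (s_ph == "ns" && s_mp == "M>P" && s_mh == "H<M") {
    "ELD_P_low"
  } else if (s_mp == "M>P" && s_mh == "H<M" && s_ph == "H>P") {
    "additive_M_gt_P"
  } else if (s_mp == "M<P" && s_mh == "H>M" && s_ph == "H<P") {
    "additive_M_lt_P"
  } else if (s_mp == "ns" && s_mh == "ns" && s_ph == "ns") {
    "additive_conserved"
  } else {
    d_add <- abs(H - (M + P) / 2)
    d_m <- abs(H - M)
    d_p <- abs(H - P)
    if (d_add <= min(d_m, d_p) || d_m == d_p) {
      if (s_mp == "M>P") "additive_M_gt_P"
      else if (s_mp == "M<P") "additive_M_lt_P"
      else "additive_conserved"
    } else if (d_m < d_p) {
      dir <- if (s_mp != "ns") s_mp else if (M > P) "M>P" else "M<P"
      if (dir == "M>P") "ELD_M_high" else "ELD_M_low"
    } else {
      dir <- if (s_mp != "ns") s_mp else if (M > P) "M>P" else "M<P"
      if (dir == "M<P") "ELD_P_high" else "ELD_P_low"
    }
  }
}
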