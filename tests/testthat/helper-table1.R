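# Published group-mean subfield volumes (mm3) used as worked-example inputs:
# left/right hemisphere for the DS and HC groups, plus the CA-total values
# used to back out the CA2+CA3 remainder.
t1means <- list(
    DS = c(erc_l = 289, sub_l = 563, ca1_l = 1021, dg_l = 571, tail_l = 110,
           erc_r = 323, sub_r = 483, ca1_r = 1220, dg_r = 616, tail_r = 86),
    HC = c(erc_l = 368, sub_l = 653, ca1_l = 1446, dg_l = 810, tail_l = 156,
           erc_r = 371, sub_r = 555, ca1_r = 1614, dg_r = 844, tail_r = 121))
t1cat <- list(DS = c(cat_l = 1048, cat_r = 1230),
              HC = c(cat_l = 1496, cat_r = 1636))

t1row <- function(g) {
    m <- t1means[[g]]
    # CA2/CA3 carry the CAt - CA1 remainder, split arbitrarily
    data.frame(sub_l = m[["sub_l"]], ca1_l = m[["ca1_l"]],
               ca2_l = t1cat[[g]][["cat_l"]] - m[["ca1_l"]], ca3_l = 0,
               dg_l = m[["dg_l"]], tail_l = m[["tail_l"]],
               sub_r = m[["sub_r"]], ca1_r = m[["ca1_r"]],
               ca2_r = t1cat[[g]][["cat_r"]] - m[["ca1_r"]], ca3_r = 0,
               dg_r = m[["dg_r"]], tail_r = m[["tail_r"]])
}
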