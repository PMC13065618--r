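# Independent re-implementation of the descriptor panel: plain loops and
# base aggregation only, sharing no code with the package internals. Used
# as the second route in dual-implementation checks.
oracle_features <- function(rec) {
  trs <- Filter(function(tr) length(tr$t) >= 3, rec$tracks)
  per <- lapply(trs, function(tr) {
    vx <- ax <- c()
    for (i in seq_len(length(tr$t) - 1))
      vx[i] <- (tr$x[i + 1] - tr$x[i]) / (tr$t[i + 1] - tr$t[i])
    for (i in seq_len(length(tr$t) - 2))
      ax[i] <- (vx[i + 1] - vx[i]) / (tr$t[i + 1] - tr$t[i])
    dv <- diff(vx)
    list(mv = mean(abs(vx)), ma = mean(ax), maa = mean(abs(ax)),
         np = sum(dv > 0), nn = sum(dv < 0))
  })
  mv <- sapply(per, `[[`, "mv"); ma <- sapply(per, `[[`, "ma")
  maa <- sapply(per, `[[`, "maa")
  vbin <- findInterval(mv, c(0, 500, 1000, 1500)); vbin[vbin < 1] <- 1
  abin <- findInterval(ma, c(-5000, 0, 5000)) + 1
  vr <- sapply(1:4, function(b) if (any(vbin == b)) mean(mv[vbin == b]) else 0)
  ar <- sapply(1:4, function(b) if (any(abin == b)) mean(ma[abin == b]) else 0)
  Rp <- mean(sapply(per, `[[`, "np")); Rn <- mean(sapply(per, `[[`, "nn"))
  c(v_ave = mean(mv), v_med = median(mv),
    v_0_500 = vr[1], v_500_1000 = vr[2], v_1000_1500 = vr[3], v_1500_inf = vr[4],
    a_ave = mean(maa), a_med = median(ma),
    ratio_va_ave = mean(mv) / mean(maa), ratio_va_med = median(mv) / median(ma),
    prod_va_ave = mean(mv) * mean(maa), prod_va_med = median(mv) * median(ma),
    a_minf_m5000 = ar[1], a_m5000_0 = ar[2], a_0_5000 = ar[3], a_5000_inf = ar[4],
    R_pos = Rp, R_neg = Rn, R_ratio = Rp / Rn,
    s_vx = sd(mv), s_ax = sd(ma), ratio_s = sd(mv) / sd(ma),
    prod_s = sd(mv) * sd(ma), ratio_vave_svx = mean(mv) / sd(mv),
    ratio_aave_sax = mean(maa) / sd(ma),
    prod_v_0_500_x_500_1000 = vr[1] * vr[2],
    prod_v_0_500_x_1000_1500 = vr[1] * vr[3],
    prod_v_0_500_x_1500_inf = vr[1] * vr[4],
    prod_v_500_1000_x_1000_1500 = vr[2] * vr[3],
    prod_v_500_1000_x_1500_inf = vr[2] * vr[4],
    prod_v_1000_1500_x_1500_inf = vr[3] * vr[4],
    prod_a_minf_m5000_x_m5000_0 = ar[1] * ar[2],
    prod_a_minf_m5000_x_0_5000 = ar[1] * ar[3],
    prod_a_minf_m5000_x_5000_inf = ar[1] * ar[4],
    prod_a_m5000_0_x_0_5000 = ar[2] * ar[3],
    prod_a_m5000_0_x_5000_inf = ar[2] * ar[4],
    prod_a_0_5000_x_5000_inf = ar[3] * ar[4],
    N_v_0_500 = sum(vbin == 1), N_v_500_1000 = sum(vbin == 2),
    N_v_1000_1500 = sum(vbin == 3), N_v_1500_inf = sum(vbin == 4),
    N_a_minf_m5000 = sum(abin == 1), N_a_m5000_0 = sum(abin == 2),
    N_a_0_5000 = sum(abin == 3), N_a_5000_inf = sum(abin == 4))
}
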