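name,family,units,description
rolling_velocity,classical,um/s,Mean velocity of the first up-to-53 cells crossing a 100 um segment
rolling_flux,classical,cells,Distinct cells dwelling in the region of interest for more than 60 s
adhesion,classical,cells,Stationary cells (>= 30 s) extrapolated to the 8.77 mm2 dish surface
v_ave,velocity,um/s,Mean over cells of the mean absolute per-frame velocity along x
v_med,velocity,um/s,Median over cells of the mean absolute per-frame velocity along x
v_0_500,velocity,um/s,Mean per-cell velocity of cells in the 0-500 um/s bin
v_500_1000,velocity,um/s,Mean per-cell velocity of cells in the 500-1000 um/s bin
v_1000_1500,velocity,um/s,Mean per-cell velocity of cells in the 1000-1500 um/s bin
v_1500_inf,velocity,um/s,Mean per-cell velocity of cells in the 1500-inf um/s bin
a_ave,acceleration,um/s2,Mean over cells of the mean absolute per-frame acceleration
a_med,acceleration,um/s2,Median over cells of the mean signed per-frame acceleration
ratio_va_ave,acceleration,s,Ratio of average velocity to average acceleration
ratio_va_med,acceleration,s,Ratio of median velocity to median acceleration
prod_va_ave,acceleration,um2/s3,Product of average velocity and average acceleration
prod_va_med,acceleration,um2/s3,Product of median velocity and median acceleration
a_minf_m5000,acceleration,um/s2,Mean per-cell acceleration of cells in the (-inf)-(-5000) bin
a_m5000_0,acceleration,um/s2,Mean per-cell acceleration of cells in the (-5000)-0 bin
a_0_5000,acceleration,um/s2,Mean per-cell acceleration of cells in the 0-5000 bin
a_5000_inf,acceleration,um/s2,Mean per-cell acceleration of cells in the 5000-inf bin
R_pos,rolling,events,Average number of positive rolling events (accelerations) per cell
R_neg,rolling,events,Average number of negative rolling events (decelerations) per cell
R_ratio,rolling,1,Ratio of positive to negative rolling events
s_vx,sd,um/s,Standard deviation of the per-cell mean velocity
s_ax,sd,um/s2,Standard deviation of the per-cell mean signed acceleration
ratio_s,sd,s,Ratio of velocity SD to acceleration SD
prod_s,sd,um2/s3,Product of velocity SD and acceleration SD
ratio_vave_svx,sd,1,Ratio of average velocity to its SD
ratio_aave_sax,sd,1,Ratio of average acceleration to its SD
prod_v_0_500_x_500_1000,interaction,um2/s2,Product of the 0-500 and 500-1000 velocity-range features
prod_v_0_500_x_1000_1500,interaction,um2/s2,Product of the 0-500 and 1000-1500 velocity-range features
prod_v_0_500_x_1500_inf,interaction,um2/s2,Product of the 0-500 and 1500-inf velocity-range features
prod_v_500_1000_x_1000_1500,interaction,um2/s2,Product of the 500-1000 and 1000-1500 velocity-range features
prod_v_500_1000_x_1500_inf,interaction,um2/s2,Product of the 500-1000 and 1500-inf velocity-range features
prod_v_1000_1500_x_1500_inf,interaction,um2/s2,Product of the 1000-1500 and 1500-inf velocity-range features
prod_a_minf_m5000_x_m5000_0,interaction,um2/s4,Product of the (-inf)-(-5000) and (-5000)-0 acceleration-range features
prod_a_minf_m5000_x_0_5000,interaction,um2/s4,Product of the (-inf)-(-5000) and 0-5000 acceleration-range features
prod_a_minf_m5000_x_5000_inf,interaction,um2/s4,Product of the (-inf)-(-5000) and 5000-inf acceleration-range features
prod_a_m5000_0_x_0_5000,interaction,um2/s4,Product of the (-5000)-0 and 0-5000 acceleration-range features
prod_a_m5000_0_x_5000_inf,interaction,um2/s4,Product of the (-5000)-0 and 5000-inf acceleration-range features
prod_a_0_5000_x_5000_inf,interaction,um2/s4,Product of the 0-5000 and 5000-inf acceleration-range features
N_v_0_500,count,cells,Number of cells in the 0-500 um/s velocity bin
N_v_500_1000,count,cells,Number of cells in the 500-1000 um/s velocity bin
N_v_1000_1500,count,cells,Number of cells in the 1000-1500 um/s velocity bin
N_v_1500_inf,count,cells,Number of cells in the 1500-inf um/s velocity bin
N_a_minf_m5000,count,cells,Number of cells in the (-inf)-(-5000) acceleration bin
N_a_m5000_0,count,cells,Number of cells in the (-5000)-0 acceleration bin
N_a_0_5000,count,cells,Number of cells in the 0-5000 acceleration bin
N_a_5000_inf,count,cells,Number of cells in the 5000-inf acceleration bin
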