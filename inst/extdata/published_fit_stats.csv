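# Published fit statistics for the six equations on the log scale (adjusted
# R-squared, root mean square error of ln leaf mass, AIC as printed by the
# source software). The packaged coefficient sets use rmse^2 as the log-scale
# residual-variance proxy for the Baskerville back-transformation correction,
# because no residual variance is printed alongside the coefficients.
equation,adj_r2,rmse,aic
eq1,0.86,0.50,5338.36
eq2,0.87,0.50,5287.48
eq3,0.74,0.69,7670.81
eq4,0.79,0.63,6925.52
eq5,0.80,0.62,6809.51
eq6,0.86,0.51,5500.63
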