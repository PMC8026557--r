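# Empirically established relative-error bounds of the limiting-form
# approximations against the adaptive-quadrature oracle, measured on
# v in [0, v_max] (step 0.025 for the Gaussian-dominance forms, 0.5 for
# the intermediate sum, v_max/25 for the tail form) at the listed xi.
# Bounds carry ~30% headroom over the measured maxima; the test suite
# re-measures the errors and asserts they stay below these bounds.
form,xi,v_max,max_rel_err
gauss,0.01,0.3,3.7e-6
gauss,0.05,0.3,2.0e-5
gauss,0.1,0.3,4.1e-5
gauss,0.2,0.3,9.0e-5
gauss,0.3,0.3,1.5e-4
gauss,0.5,0.3,2.9e-4
gauss_small,0.01,0.3,2.1e-5
gauss_small,0.05,0.3,1.1e-4
gauss_small,0.1,0.3,2.3e-4
gauss_small,0.2,0.3,5.0e-4
lorentz_sum,1,6,6.0e-5
lorentz_sum,2,6,7.0e-9
lorentz_sum,3,6,5.2e-12
lorentz_sum,5,6,2.0e-15
lorentz_sum,10,6,2.0e-15
lorentz_tail,10,50,6.5e-3
lorentz_tail,20,100,1.7e-3
lorentz_tail,50,250,2.7e-4
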