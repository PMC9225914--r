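# Validation series: 5 mm disk-average skin temperature during a 15-minute
# mild moxibustion (18 mm stick, 4 cm distance), published simulated values
# vs in-vivo measurements (test_pm_C is the printed +/- uncertainty).
# deviation_pct is the printed deviation, 100*(simulated - test)/simulated.
# formula_consistent flags rows whose printed deviation reproduces under
# that convention (to the printed 2 decimals): rows t=1.5 and t=2 appear
# swapped/sign-mangled in print, rows t=3.5 and t=13.5..15 reproduce only
# with the test value as denominator, and t=7.5, t=12, t=13 match neither
# convention; all ten are excluded from formula checks.
time_min,simulated_C,test_C,test_pm_C,deviation_pct,formula_consistent
0,34.30,34.3,0.4,0,TRUE
0.5,38.56,40.0,2.0,-3.73,TRUE
1,40.03,41.4,2.4,-3.42,TRUE
1.5,41.29,42.8,2.7,-1.87,FALSE
2,42.25,43.0,3.0,3.66,FALSE
2.5,42.66,43.0,2.9,-0.80,TRUE
3,43.05,43.0,3.1,0.12,TRUE
3.5,43.30,43.0,3.0,0.70,FALSE
4,43.18,44.0,2.3,-1.90,TRUE
4.5,43.06,44.1,2.3,-2.42,TRUE
5,43.07,44.6,2.9,-3.55,TRUE
5.5,43.42,44.1,3.0,-1.57,TRUE
6,43.77,44.2,2.7,-0.98,TRUE
6.5,43.97,44.2,2.5,-0.52,TRUE
7,43.75,44.4,2.2,-1.49,TRUE
7.5,43.54,44.6,2.1,-2.48,FALSE
8,43.46,44.5,2.4,-2.39,TRUE
8.5,43.75,44.7,2.6,-2.17,TRUE
9,44.05,44.9,2.3,-1.93,TRUE
9.5,44.20,44.7,1.9,-1.13,TRUE
10,43.95,44.2,1.5,-0.57,TRUE
10.5,43.70,44.2,2.3,-1.14,TRUE
11,43.59,43.9,2.5,-0.71,TRUE
11.5,43.87,44.5,2.2,-1.44,TRUE
12,44.14,44.1,1.6,0.01,FALSE
12.5,44.27,44.5,1.7,-0.52,TRUE
13,44.02,44.0,1.6,0.00,FALSE
13.5,43.76,43.4,1.7,0.83,FALSE
14,43.64,43.1,1.6,1.25,FALSE
14.5,43.91,42.6,1.1,3.08,FALSE
15,44.18,43.1,1.8,2.51,FALSE
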