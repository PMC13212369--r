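sex,age_years,q5_mm,q50_mm,q95_mm
female,0.5,4.664,8.386,11.418
female,1,6.887,10.662,13.836
female,2,11.095,15.009,18.450
female,3,14.987,19.082,22.768
female,4,18.562,22.883,26.790
female,5,21.821,26.410,30.516
female,6,24.764,29.664,33.946
female,7,27.390,32.644,37.079
female,8,29.701,35.352,39.917
female,9,31.694,37.786,42.458
female,10,33.372,39.947,44.703
female,11,34.733,41.835,46.652
male,0.5,5.097,9.202,13.031
male,1,7.397,11.420,15.425
male,2,11.713,15.640,19.952
male,3,15.649,19.571,24.130
male,4,19.204,23.212,27.959
male,5,22.379,26.565,31.438
male,6,25.174,29.628,34.567
male,7,27.589,32.402,37.347
male,8,29.624,34.887,39.778
male,9,31.278,37.083,41.859
male,10,32.552,38.990,43.591
male,11,33.446,40.608,44.974
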