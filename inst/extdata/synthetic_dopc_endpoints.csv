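"concentration_mg_per_ml","replicate","delta_f_hz"
0.025,1,-0.989208571291653
0.025,2,-2.92486518983441
0.025,3,-1.99703860710098
0.025,4,-1.72730441347728
0.025,5,-1.95589869529732
0.0571428571428571,1,-5.50079198680765
0.0571428571428571,2,-3.88314547327722
0.0571428571428571,3,-5.48932650912926
0.0571428571428571,4,-3.37624375683912
0.0571428571428571,5,-5.45738156976858
0.0892857142857143,1,-7.12429826877052
0.0892857142857143,2,-6.1425225302929
0.0892857142857143,3,-9.81802862410635
0.0892857142857143,4,-8.70795668981138
0.0892857142857143,5,-8.56248925938766
0.121428571428571,1,-10.8277179772018
0.121428571428571,2,-11.7479212966879
0.121428571428571,3,-14.1201237961766
0.121428571428571,4,-13.9041353038474
0.121428571428571,5,-10.1435550295417
0.153571428571429,1,-14.8048074216282
0.153571428571429,2,-16.2794772615297
0.153571428571429,3,-14.6700861833093
0.153571428571429,4,-13.2834941283771
0.153571428571429,5,-12.6029753662847
0.185714285714286,1,-17.9631384114337
0.185714285714286,2,-17.7899386625965
0.185714285714286,3,-19.2958323650223
0.185714285714286,4,-17.0725719249963
0.185714285714286,5,-18.1726641557877
0.217857142857143,1,-20.1117196088642
0.217857142857143,2,-19.8623323948766
0.217857142857143,3,-19.5320662101355
0.217857142857143,4,-21.1760961075126
0.217857142857143,5,-20.0622146088074
0.25,1,-25.3186788634566
0.25,2,-24.3861291927627
0.25,3,-24.4525777785597
0.25,4,-26.0158778343298
0.25,5,-23.565547577491
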