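lat	lon	x	y
0	0	0.000000000	0.000000000
45	10	823606.029555533	5549500.274000579
-45	-10	-823606.029555533	-5549500.274000579
89.9	179.9	8466131.235576300	8451120.807829516
-89.9	-179.9	-8466131.235576300	-8451120.807829516
90	0	0.000000000	8451143.753515257
-90	0	0.000000000	-8451143.753515257
23.4365	-120.75	-10960712.048790371	3033867.016215787
66.5	30.25	2075872.963720853	7496852.379640475
0	0.5	46950.798630640	0.000000000
49.31208874007339	-46.51271127627075	-3722842.804149442	5995733.485327096
-11.001880844630577	153.63539598549664	14320638.887732461	-1443292.240329247
64.54762558404883	51.79144322903923	3630481.515581721	7352686.382990527
35.526245230685504	116.19418077749879	10075234.335558694	4494806.276917339
-73.04807738022308	-20.37088842216079	-1290175.268977893	-7919917.126336415
85.61202329461608	-98.19406015748032	-5066554.312607585	8409655.008533509
47.005146358263545	19.650523325700533	1597741.844590348	5759916.658781583
51.491574949851696	-157.0257878024969	-12371142.046206662	6211997.179566480
-66.93954611840175	117.94722191732956	8054093.335788828	-7528229.676594717
-8.93053117879792	47.399183683943335	4429316.843819515	-1173046.355343982
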