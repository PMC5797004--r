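mirna	log2fc_invitro	log2fc_invivo	adj_p
hsa-miR-483-5p	-8.5	-6.9	0.00000
hsa-miR-483-3p	-3.2	-4.5	0.00000
hsa-miR-18a-3p	-10.6	-2.3	0.00023
hsa-miR-618	-1.2	-1.7	0.03615
hsa-miR-486-3p	-1.8	-1.6	0.01404
hsa-miR-1254	-1.1	-1.5	0.01257
hsa-miR-1247-5p	-2.5	-1.4	0.01087
hsa-miR-875-5p	-16.1	-1.4	0.03615
hsa-miR-939-5p	-2.4	-1.4	0.03615
hsa-miR-7-1-3p	-1.1	-1.4	0.00452
hsa-miR-454-5p	-1.6	-1.2	0.00356
hsa-miR-1276	-8.9	-1.2	0.03128
hsa-miR-543	-3.7	-1.2	0.03615
hsa-miR-30e-3p	-2.1	-1.2	0.00066
hsa-miR-30c-2-3p	-2.8	-1.1	0.00042
hsa-miR-29c-5p	1.3	2.0	0.03128
hsa-miR-655-3p	9.8	2.2	0.00131
hsa-miR-145-5p	16.4	2.2	0.00011
hsa-miR-10b-5p	1.1	2.3	0.00001
hsa-miR-615-3p	1.6	2.7	0.00000
hsa-miR-9-5p	1.2	2.8	0.00218
hsa-miR-22-5p	1.5	3.0	0.00001
hsa-miR-15a-5p	4.7	3.2	0.00000
hsa-miR-758-3p	3.6	3.7	0.00001
hsa-miR-382-5p	5.3	4.0	0.00016
hsa-miR-183-3p	5.2	4.2	0.00002
hsa-miR-223-3p	8.7	4.2	0.00000
hsa-miR-335-3p	2.1	4.3	0.00000
hsa-miR-582-5p	8.4	4.5	0.00031
hsa-miR-154-5p	1.1	4.5	0.00000
hsa-miR-190a-5p	4.5	5.0	0.00000
hsa-miR-375	30.8	5.1	0.00000
hsa-miR-769-5p	12.1	7.0	0.00000
hsa-miR-889-3p	2.6	7.1	0.00000
hsa-miR-654-3p	5.8	7.5	0.00000
hsa-miR-92a-3p	12.4	9.2	0.00000
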