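trio	paternal_transmission	maternal_transmission	inheritance
1	0.277	0.270	0.549
2	0.414	0.352	0.453
3	0.351	0.519	0.524
4	0.370	0.369	0.356
5	0.396	0.714	0.417
6	0.373	0.448	0.576
7	0.393	0.382	0.570
8	0.428	0.403	0.482
9	0.428	0.367	0.603
10	0.401	0.390	0.441
11	0.360	0.408	0.668
12	0.335	0.343	0.594
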