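id,dimension,true_mm,est_mm,accuracy_pct
1,length,92,109,84.4
1,width,78,60,70.0
1,height,56,39,56.4
2,length,92,116,79.3
2,width,75,82,91.5
2,height,54,52,96.2
3,length,92,99,92.9
3,width,79,88,89.8
3,height,54,52,96.2
4,length,117,100,83.0
4,width,93,88,94.3
4,height,55,53,96.2
5,length,102,107,95.3
5,width,94,100,94.0
5,height,63,60,95.0
6,length,96,75,72.0
6,width,77,63,77.8
6,height,58,33,24.2
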