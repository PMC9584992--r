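id,aMDRD,CKD-EPI-cr,CKD-EPI-cy,CKD-EPI-cr-cy,Cockcroft-Gault,FAS-cr,FAS-cy,FAS-cr-cy,Lund-Malmo (Rv),Grubb-2014 (CAPA),Hoek,Larsson
A,89.4765,101.3345,104.7572,103.1042,100.0000,104.4074,105.6964,105.0480,90.7634,94.5979,91.8528,88.2271
B,71.1880,80.6006,62.3146,70.2501,79.6875,78.0187,66.4679,71.7816,75.0487,63.0892,64.4376,68.4845
C,56.5275,59.0683,58.8916,58.4768,62.9630,59.8805,58.4548,59.1591,56.4223,58.2514,62.8446,50.5109
D,108.4551,113.0108,108.5515,113.5926,119.0394,115.6636,116.1357,115.8992,100.4542,111.6624,102.0652,121.1644
E,24.5197,23.6138,28.4856,25.3819,26.3095,25.6710,34.4873,29.4331,22.0088,29.4968,35.2719,28.5497
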