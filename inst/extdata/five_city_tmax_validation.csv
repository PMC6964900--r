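city,product,mean_diff,rmsd,n
Atlanta GA,coarse_12km,0.56,1.87,276
San Francisco CA,coarse_12km,-3.69,4.44,276
Washington DC,coarse_12km,-0.53,1.52,276
Baltimore MD,coarse_12km,-1.11,1.96,276
St. Louis MO,coarse_12km,0.02,1.96,276
Atlanta GA,downscaled_1km,1.09,2.05,276
San Francisco CA,downscaled_1km,-1.79,3.05,276
Washington DC,downscaled_1km,-0.25,1.45,276
Baltimore MD,downscaled_1km,-0.17,1.63,276
St. Louis MO,downscaled_1km,1.45,2.38,276
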