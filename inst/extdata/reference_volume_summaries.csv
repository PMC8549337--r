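injected_ul,kv,n,mean_ul,sd_ul,norm_lower_printed,norm_upper_printed,ratio_printed
10,70,25,89.46,10.14,69.57,109.38,8.9
10,100,25,73.40,8.39,56.94,89.86,7.3
10,120,25,67.48,7.33,53.11,81.86,6.7
20,70,25,148.10,21.71,105.54,190.66,7.4
20,100,25,125.10,18.41,89.00,161.19,6.2
20,120,25,117.14,16.76,84.29,149.99,5.8
30,70,25,214.80,36.87,142.52,287.07,7.2
30,100,25,188.83,31.20,127.67,249.99,6.3
30,120,25,176.48,29.65,118.36,234.59,5.9
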