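strain,species,salinity,growth_rate_per_day,end_density_cells_per_ml
PLY B11,E. huxleyi,25,0.194,1.0e6
PLY B11,E. huxleyi,34,0.135,9.4e5
PLY B11,E. huxleyi,44,0.184,1.6e6
RCC 868,E. huxleyi,25,0.182,1.8e6
RCC 868,E. huxleyi,34,0.402,7.2e5
RCC 868,E. huxleyi,44,0.223,1.5e6
RCC 1210,E. huxleyi,25,0.286,1.1e6
RCC 1210,E. huxleyi,34,0.601,2.1e6
RCC 1210,E. huxleyi,44,0.207,1.7e6
RCC 1223,G. oceanica,25,0.240,1.6e6
RCC 1223,G. oceanica,34,0.065,1.4e6
RCC 1223,G. oceanica,44,0.170,2.5e6
RCC 1232,E. huxleyi,25,0.226,1.4e6
RCC 1232,E. huxleyi,34,0.302,9.3e5
RCC 1232,E. huxleyi,44,0.191,2.4e6
RCC 1824,E. huxleyi,25,0.184,9.4e5
RCC 1824,E. huxleyi,34,0.371,3.3e5
RCC 1824,E. huxleyi,44,0.193,1.4e6
RCC 1843,E. huxleyi,25,0.234,1.0e6
RCC 1843,E. huxleyi,34,0.038,5.3e5
RCC 1843,E. huxleyi,44,0.089,5.5e6
SAG 33.90,E. huxleyi,25,0.409,1.7e6
SAG 33.90,E. huxleyi,34,0.313,6.5e5
SAG 33.90,E. huxleyi,44,0.245,2.2e6
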