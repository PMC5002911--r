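muscle,parameter,visit,mean,sd,cv,paired_p
gastrocnemius,phv,1,7.4,3.5,47.1,0.4
gastrocnemius,phv,2,6.2,3.0,48.2,0.4
soleus,phv,1,12.9,5.8,45.0,0.4
soleus,phv,2,10.4,4.6,44.0,0.4
anterior_tibialis,phv,1,7.7,4.0,52.1,0.9
anterior_tibialis,phv,2,8.0,3.9,48.6,0.9
peroneus_longus,phv,1,9.2,5.1,55.2,0.2
peroneus_longus,phv,2,6.7,1.8,26.2,0.2
gastrocnemius,miv,1,-13.3,4.3,32.7,0.1
gastrocnemius,miv,2,-10.2,3.1,30.1,0.1
soleus,miv,1,-12.4,6.4,51.7,0.4
soleus,miv,2,-10.4,3.7,36.1,0.4
anterior_tibialis,miv,1,-7.5,3.4,45.5,0.4
anterior_tibialis,miv,2,-6.1,2.1,34.9,0.4
peroneus_longus,miv,1,-9.4,5.5,58.8,0.2
peroneus_longus,miv,2,-6.3,1.8,29.5,0.2
gastrocnemius,ttp,1,28.5,5.6,19.5,0.7
gastrocnemius,ttp,2,29.3,15.9,20.3,0.7
soleus,ttp,1,21.0,2.8,13.2,0.9
soleus,ttp,2,21.4,7.9,37.1,0.9
anterior_tibialis,ttp,1,26.3,5.0,19.1,0.4
anterior_tibialis,ttp,2,28.6,9.5,33.2,0.4
peroneus_longus,ttp,1,25.1,6.6,26.3,0.3
peroneus_longus,ttp,2,29.3,8.3,28.4,0.3
gastrocnemius,ttr,1,129.4,28.5,22.1,0.6
gastrocnemius,ttr,2,134.6,37.8,28.1,0.6
soleus,ttr,1,134.1,21.5,16.0,0.7
soleus,ttr,2,139.5,55.6,39.8,0.7
anterior_tibialis,ttr,1,136.5,40.2,29.4,0.5
anterior_tibialis,ttr,2,153.4,52.7,34.3,0.5
peroneus_longus,ttr,1,140.6,48.4,34.4,0.5
peroneus_longus,ttr,2,124.9,30.2,24.2,0.5
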