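compound_id,homo_ev,lumo_ev,gap_ev,ionization_ev,affinity_ev,electronegativity_ev,chemical_potential_ev,hardness_ev,softness_inv_ev,electrophilicity_ev
10a,-5.9243,-2.1605,3.7638,5.9243,2.1605,4.0424,-4.0424,1.8819,0.5314,4.3417
10b,-5.8984,-2.1638,3.7346,5.8984,2.1638,4.0311,-4.0311,1.8673,0.5355,4.3511
10c,-5.7478,-2.2872,3.4606,5.7478,2.2872,4.0175,-4.0175,1.7303,0.5779,4.664
10d,-5.7264,-2.1738,3.5527,5.7264,2.1738,3.9501,-3.9501,1.7763,0.563,4.392
10e,-5.8874,-2.838,3.0494,5.8874,2.838,4.3627,-4.3627,1.5247,0.6559,6.2415
10f,-5.8528,-2.4932,3.3596,5.8528,2.4932,4.173,-4.173,1.6798,0.5953,5.1833
10g,-5.8649,-2.5013,3.3637,5.8649,2.5013,4.1831,-4.1831,1.6818,0.5946,5.2022
10h,-5.5547,-3.6823,1.8725,5.5547,3.6823,4.6185,-4.6185,0.9362,1.0681,11.392
10i,-5.8863,-2.0045,3.8818,5.8863,2.0045,3.9454,-3.9454,1.9409,0.5152,4.01
10j,-5.8604,-2.0166,3.8437,5.8604,2.0166,3.9385,-3.9385,1.9219,0.5203,4.0356
10k,-5.8528,-2.0156,3.8372,5.8528,2.0156,3.9342,-3.9342,1.9186,0.5212,4.0335
10l,-5.8892,-2.0663,3.8229,5.8892,2.0663,3.9778,-3.9778,1.9115,0.5232,4.1389
10m,-5.8741,-2.0156,3.8586,5.8741,2.0156,3.9448,-3.9448,1.9293,0.5183,4.033
10n,-5.8693,-2.0191,3.8502,5.8693,2.0191,3.9442,-3.9442,1.9251,0.5195,4.0404
10o,-5.8712,-2.0177,3.8534,5.8712,2.0177,3.9444,-3.9444,1.9267,0.519,4.0376
10p,-5.4157,-3.6086,1.8071,5.4157,3.6086,4.5121,-4.5121,0.9036,1.1067,11.266
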