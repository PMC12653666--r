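device,parameter,mean_affected,sd_affected,mean_unaffected,sd_unaffected,reported_effect,reported_p
goniometer,P1,0.74,0.26,1.11,0.14,-0.37,<0.0001
goniometer,P2,28.4,7.98,32.9,9.4,-4.49,0.0892
goniometer,P3,0.87,0.27,1.18,0.12,-0.31,0.0003
pose2d,P1,0.69,0.23,1.06,0.1,-0.37,<0.0001
pose2d,P2,27.2,6.57,28.7,8.48,-1.49,0.606
pose2d,P3,0.87,0.27,1.18,0.18,-0.31,0.0017
pose3d,P1,0.73,0.29,1.07,0.13,-0.34,<0.0001
pose3d,P2,21.7,6.94,24.0,6.57,-2.34,0.28
pose3d,P3,0.87,0.3,1.23,0.14,-0.35,<0.0001
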